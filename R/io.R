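#' Write a pseudobulk cohort to disk
#'
#' One MatrixMarket counts file per view (genes as columns), with sample and
#' gene index TSVs, plus `meta.tsv` and `cell_counts.tsv`.
#'
#' @param pb a `pseudobulk_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(pb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(pb$views)) {
    v <- pb$views[[ct]]
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE),
                    file.path(dir, paste0(ct, ".mtx")))
    utils::write.table(data.frame(sample = rownames(v)),
                       file.path(dir, paste0(ct, ".samples.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(gene = colnames(v)),
                       file.path(dir, paste0(ct, ".genes.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(pb$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(celltype = rownames(pb$cell_counts),
                                pb$cell_counts, check.names = FALSE),
                     file.path(dir, "cell_counts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a pseudobulk cohort written by [write_cohort()]
#'
#' @param dir directory containing the MTX and TSV files.
#' @return A `pseudobulk_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "meta.tsv"),
                            stringsAsFactors = FALSE)
  cc <- utils::read.delim(file.path(dir, "cell_counts.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  cell_counts <- as.matrix(cc[, -1L, drop = FALSE])
  rownames(cell_counts) <- cc$celltype
  mtx <- list.files(dir, pattern = "\\.mtx$")
  views <- list()
  for (f in mtx) {
    ct <- sub("\\.mtx$", "", f)
    m <- as.matrix(Matrix::readMM(file.path(dir, f)))
    rownames(m) <- utils::read.delim(
      file.path(dir, paste0(ct, ".samples.tsv")))$sample
    colnames(m) <- utils::read.delim(
      file.path(dir, paste0(ct, ".genes.tsv")))$gene
    views[[ct]] <- m
  }
  new_pseudobulk_cohort(views, meta, cell_counts)
}

#' Write weighted gene sets in a GMT-like text format
#'
#' One line per set: `set_id <TAB> description <TAB> gene:weight ...`.
#'
#' @param sets named list of named numeric weight vectors.
#' @param path output file.
#' @param descriptions optional character vector per set.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    gw <- sets[[i]]
    paste(c(names(sets)[i], descriptions[i],
            paste0(names(gw), ":", format(gw, digits = 10, trim = TRUE))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read weighted gene sets written by [write_gene_sets()]
#'
#' @param path input file.
#' @return Named list of named numeric weight vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    gw <- strsplit(parts[-(1:2)], ":", fixed = TRUE)
    sets[[parts[1L]]] <- setNames(
      vapply(gw, function(x) as.numeric(x[2L]), numeric(1)),
      vapply(gw, `[[`, character(1), 1L))
  }
  sets
}

#' Write a factor model's loadings, scores and variance table as TSV
#'
#' @param model a `factor_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(model$w))
    utils::write.table(data.frame(gene = rownames(model$w[[ct]]),
                                  model$w[[ct]], check.names = FALSE),
                       file.path(dir, paste0("loadings_", ct, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(model$z))
    utils::write.table(data.frame(sample = rownames(model$z[[g]]),
                                  model$z[[g]], check.names = FALSE),
                       file.path(dir, paste0("scores_", g, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(model$r2, file.path(dir, "r2.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
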