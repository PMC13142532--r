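#' Construct a pseudobulk cohort container
#'
#' A `pseudobulk_cohort` holds one sample-by-gene count matrix per cell type
#' (a "view"), per-sample metadata, and per-(cell type, sample) cell counts.
#' Views may cover different sample subsets (quality control is per view),
#' but every view's samples must appear in `meta`.
#'
#' @param views named list of sample x gene non-negative count matrices.
#' @param meta data.frame with a `sample_id` column and clinical covariates.
#' @param cell_counts celltype x sample matrix of contributing cell numbers
#'   (optional; zeros assumed when absent).
#' @return An object of class `pseudobulk_cohort`.
#' @export
new_pseudobulk_cohort <- function(views, meta, cell_counts = NULL) {
  stopifnot(is.list(views), !is.null(names(views)))
  if (!"sample_id" %in% names(meta)) .stopf("meta must have a sample_id column")
  for (ct in names(views)) {
    v <- views[[ct]]
    if (any(v < 0)) .stopf("negative counts in view '%s'", ct)
    if (!all(rownames(v) %in% meta$sample_id))
      .stopf("view '%s' has samples missing from meta", ct)
  }
  if (is.null(cell_counts)) {
    cell_counts <- matrix(0L, length(views), nrow(meta),
                          dimnames = list(names(views), meta$sample_id))
  }
  total_counts <- do.call(rbind, lapply(views, function(v) {
    tc <- setNames(rep(0, nrow(meta)), meta$sample_id)
    tc[rownames(v)] <- rowSums(v)
    tc
  }))
  structure(list(views = views, meta = meta, cell_counts = cell_counts,
                 total_counts = total_counts),
            class = "pseudobulk_cohort")
}

#' @export
print.pseudobulk_cohort <- function(x, ...) {
  cat(sprintf("pseudobulk_cohort: %d views, %d samples\n",
              length(x$views), nrow(x$meta)))
  for (ct in names(x$views))
    cat(sprintf("  %s: %d samples x %d genes\n", ct,
                nrow(x$views[[ct]]), ncol(x$views[[ct]])))
  invisible(x)
}

#' Aggregate single-cell counts into per-cell-type pseudobulk views
#'
#' Sums raw counts over all cells sharing a (cell type, sample) pair. Pairs
#' with no cells yield no row (they are absent, not zero-filled), and their
#' cell count is recorded as 0.
#'
#' @param cells cell x gene count matrix.
#' @param celltype_labels character vector, one per cell row.
#' @param sample_labels character vector, one per cell row.
#' @param meta optional per-sample metadata; a minimal frame is built from
#'   `sample_labels` when absent.
#' @return A `pseudobulk_cohort`.
#' @export
aggregate_pseudobulk <- function(cells, celltype_labels, sample_labels,
                                 meta = NULL) {
  if (length(celltype_labels) != nrow(cells) ||
      length(sample_labels) != nrow(cells))
    .stopf("labels must align with cell rows")
  cts <- sort(unique(celltype_labels))
  samples <- sort(unique(sample_labels))
  if (is.null(meta))
    meta <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  cell_counts <- matrix(0L, length(cts), length(samples),
                        dimnames = list(cts, samples))
  views <- list()
  for (ct in cts) {
    sel <- celltype_labels == ct
    sub <- cells[sel, , drop = FALSE]
    lab <- sample_labels[sel]
    agg <- rowsum(sub, group = lab)
    agg <- agg[order(rownames(agg)), , drop = FALSE]
    views[[ct]] <- agg
    tab <- table(lab)
    cell_counts[ct, names(tab)] <- as.integer(tab)
  }
  new_pseudobulk_cohort(views, meta, cell_counts)
}

#' Sample-level pseudobulk quality control
#'
#' Within each view, a sample is retained iff it aggregates at least
#' `min_cells` cells and at least `min_counts` total counts (both thresholds
#' inclusive). Filtering is per (cell type, sample), so views may end with
#' different sample subsets.
#'
#' @param pb a `pseudobulk_cohort` with cell counts.
#' @param min_cells minimum number of cells (default 10).
#' @param min_counts minimum total counts (default 1000).
#' @return The filtered `pseudobulk_cohort`.
#' @export
qc_filter_samples <- function(pb, min_cells = 10, min_counts = 1000) {
  stopifnot(inherits(pb, "pseudobulk_cohort"))
  views <- lapply(names(pb$views), function(ct) {
    v <- pb$views[[ct]]
    keep <- pb$cell_counts[ct, rownames(v)] >= min_cells &
      rowSums(v) >= min_counts
    v[keep, , drop = FALSE]
  })
  names(views) <- names(pb$views)
  new_pseudobulk_cohort(views, pb$meta, pb$cell_counts)
}

#' Gene-level pseudobulk quality control
#'
#' A gene is kept iff its maximum count over samples is at least `min_count`
#' and its total over samples is at least `min_total`. The default
#' parameterization (10/15) is the factor-model input filter; the
#' differential-expression variant uses 5/10.
#'
#' @param view sample x gene non-negative count matrix.
#' @param min_count minimum count required in at least one sample.
#' @param min_total minimum cumulative count across samples.
#' @return Character vector of retained gene names.
#' @export
qc_filter_genes <- function(view, min_count = 10, min_total = 15) {
  if (nrow(view) == 0L || ncol(view) == 0L) {
    .warnf("empty view: no genes retained")
    return(character())
  }
  mx <- apply(view, 2L, max)
  tot <- colSums(view)
  colnames(view)[mx >= min_count & tot >= min_total]
}

# standardized dispersion of log1p-CPM within one batch: residual of a
# quadratic mean-variance trend, scaled by its MAD
.hvg_dispersion <- function(logcpm) {
  m <- colMeans(logcpm)
  v <- apply(logcpm, 2L, var)
  fit <- lm(v ~ m + I(m^2))
  r <- resid(fit)
  s <- stats::mad(r)
  if (s == 0) s <- sd(r)
  if (is.na(s) || s == 0) s <- 1
  r / s
}

#' Select factor-model input genes for one view
#'
#' Highly variable genes are ranked per batch by standardized dispersion of
#' log1p counts-per-million (a gene qualifies if it is among the top `n_hvg`
#' in any batch); the result is intersected with the QC-passed gene set and
#' the top `n_markers_drop` cell-identity marker genes are removed.
#'
#' @param view sample x gene count matrix (already sample-QC'd).
#' @param batch_labels batch/group label per sample.
#' @param n_hvg number of highly variable genes per batch.
#' @param marker_ranks character vector of marker genes ordered by rank
#'   (strongest first); may be `NULL`.
#' @param n_markers_drop number of top markers to remove (default 25).
#' @return Character vector of selected gene names.
#' @export
select_model_genes <- function(view, batch_labels, n_hvg,
                               marker_ranks = NULL, n_markers_drop = 25) {
  stopifnot(nrow(view) == length(batch_labels))
  qc <- qc_filter_genes(view)
  if (n_hvg >= ncol(view)) {
    .warnf("n_hvg >= number of genes; returning all QC-passed genes")
    hvg <- colnames(view)
  } else {
    libsize <- pmax(rowSums(view), 1)
    logcpm <- log1p(view / libsize * 1e6)
    hvg <- character()
    for (b in unique(batch_labels)) {
      sub <- logcpm[batch_labels == b, , drop = FALSE]
      if (nrow(sub) < 3L) next
      disp <- .hvg_dispersion(sub)
      hvg <- union(hvg, names(sort(disp, decreasing = TRUE))[seq_len(n_hvg)])
    }
  }
  keep <- intersect(hvg, qc)
  if (n_markers_drop > 0 && length(marker_ranks))
    keep <- setdiff(keep, head(marker_ranks, n_markers_drop))
  keep
}

#' Normalize a pseudobulk view for factor-model input
#'
#' Pseudobulk counts are multiplicative in the latent programs (an
#' exponential mean model), so factorization operates on log-transformed
#' expression. `"log1p"` applies `log(1 + count)`; `"log1p_cpm"` first
#' scales each sample to counts per million.
#'
#' @param view sample x gene count matrix.
#' @param method `"log1p"` (default) or `"log1p_cpm"`.
#' @return Normalized matrix of the same shape.
#' @export
normalize_pseudobulk <- function(view, method = c("log1p", "log1p_cpm")) {
  method <- match.arg(method)
  if (method == "log1p_cpm") {
    libsize <- pmax(rowSums(view), 1)
    view <- view / libsize * 1e6
  }
  log1p(view)
}

#' Centered log-ratio transform of cell-type compositions
#'
#' Counts are row-normalized to proportions; zero entries are replaced
#' multiplicatively (delta = 1e-6 times the row's minimum nonzero
#' proportion, with nonzero entries rescaled so the row still sums to 1)
#' before the CLR transform.
#'
#' @param counts_per_type sample x celltype count (or proportion) matrix.
#' @return A list of class `composition_matrix`: `proportions` (rows sum
#'   to 1) and `clr` (rows sum to 0).
#' @export
clr_compositions <- function(counts_per_type) {
  rs <- rowSums(counts_per_type)
  if (any(rs <= 0)) .stopf("all-zero composition row")
  p <- counts_per_type / rs
  for (i in seq_len(nrow(p))) {
    z <- p[i, ] == 0
    if (any(z)) {
      delta <- 1e-6 * min(p[i, !z])
      p[i, z] <- delta
      p[i, !z] <- p[i, !z] * (1 - sum(z) * delta)
    }
  }
  lp <- log(p)
  clr <- lp - rowMeans(lp)
  structure(list(proportions = p, clr = clr), class = "composition_matrix")
}

#' Jaccard concordance of per-cell-type marker sets
#'
#' @param markers_a,markers_b named lists of gene-name character vectors.
#' @return Matrix of Jaccard indices, cell types of `markers_a` in rows.
#' @export
marker_jaccard <- function(markers_a, markers_b) {
  J <- matrix(0, length(markers_a), length(markers_b),
              dimnames = list(names(markers_a), names(markers_b)))
  for (a in names(markers_a)) for (b in names(markers_b)) {
    u <- length(union(markers_a[[a]], markers_b[[b]]))
    if (u == 0) {
      .warnf("empty union for (%s, %s); Jaccard set to 0", a, b)
      J[a, b] <- 0
    } else {
      J[a, b] <- length(intersect(markers_a[[a]], markers_b[[b]])) / u
    }
  }
  J
}

#' Cross-cohort concordance of differential-expression t-statistics
#'
#' Pearson correlation of two named t-statistic vectors over their common
#' genes.
#'
#' @param tstats_a,tstats_b named numeric vectors.
#' @return Pearson correlation coefficient.
#' @export
tstat_concordance <- function(tstats_a, tstats_b) {
  common <- intersect(names(tstats_a), names(tstats_b))
  if (length(common) < 3L) .stopf("fewer than 3 common genes")
  cor(tstats_a[common], tstats_b[common])
}
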