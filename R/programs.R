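#' Univariate linear model (ULM) activity score
#'
#' Regresses a sample's expression profile on a signed gene-weight vector
#' (weight 0 for genes outside the set), with intercept, over the whole gene
#' universe of the profile. The activity score is the slope t-statistic; the
#' p-value is two-sided from the t distribution with m - 2 degrees of
#' freedom. Equivalently, `t = r * sqrt(m - 2) / sqrt(1 - r^2)` with `r` the
#' Pearson correlation between profile and weights. A perfect fit is capped
#' at a large finite t with p ~ 0.
#'
#' @param profile named numeric vector of expression values (the universe).
#' @param gene_set named numeric vector of signed weights.
#' @param min_overlap minimum number of set genes present in the profile.
#' @return A list with `score` (t-statistic) and `p`.
#' @export
score_ulm <- function(profile, gene_set, min_overlap = 3L) {
  if (is.null(names(profile)) || is.null(names(gene_set)))
    .stopf("profile and gene_set must be named")
  matched <- intersect(names(gene_set), names(profile))
  if (length(matched) < min_overlap)
    .stopf("fewer than %d set genes present in profile", min_overlap)
  w <- setNames(numeric(length(profile)), names(profile))
  w[matched] <- gene_set[matched]
  m <- length(profile)
  if (sd(w) == 0 || sd(profile) == 0)
    .stopf("zero-variance weights or profile")
  # explicit simple-regression algebra (slope / SE of slope)
  xc <- w - mean(w)
  yc <- profile - mean(profile)
  beta <- sum(xc * yc) / sum(xc^2)
  res <- yc - beta * xc
  se2 <- sum(res^2) / ((m - 2) * sum(xc^2))
  if (se2 <= .Machine$double.eps^2 * sum(yc^2) / sum(xc^2) || se2 <= 0) {
    t_stat <- sign(beta) * 1e8
  } else {
    t_stat <- beta / sqrt(se2)
    if (!is.finite(t_stat)) t_stat <- sign(beta) * 1e8
  }
  p <- 2 * pt(-abs(t_stat), df = m - 2)
  list(score = t_stat, p = max(p, .Machine$double.xmin))
}

#' Score many samples against many weighted gene sets
#'
#' Applies [score_ulm()] per sample row and per set. Sets with fewer than
#' `min_overlap` matched genes are dropped with a warning. With
#' `zscore = TRUE` each score column is standardized across samples (the
#' convention of the dependency-network stage).
#'
#' @param mat sample x gene matrix.
#' @param gene_sets named list of weighted sets (named numeric vectors).
#' @param zscore standardize columns across samples.
#' @param min_overlap minimum matched genes per set.
#' @return A list of class `activity_matrix`: `scores` and `pvalues`
#'   (sample x set matrices).
#' @export
score_activities <- function(mat, gene_sets, zscore = FALSE,
                             min_overlap = 3L) {
  keep <- vapply(gene_sets, function(gs)
    length(intersect(names(gs), colnames(mat))) >= min_overlap, logical(1))
  if (any(!keep))
    .warnf("dropping %d set(s) with < %d matched genes", sum(!keep),
           min_overlap)
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) .stopf("no scorable gene sets")
  m <- ncol(mat)
  W <- vapply(gene_sets, function(gs) {
    w <- setNames(numeric(m), colnames(mat))
    mt <- intersect(names(gs), colnames(mat))
    w[mt] <- gs[mt]
    w
  }, numeric(m))
  # vectorized Pearson r between each sample row and each weight column
  Xc <- mat - rowMeans(mat)
  Wc <- sweep(W, 2L, colMeans(W))
  num <- Xc %*% Wc
  den <- sqrt(rowSums(Xc^2)) %o% sqrt(colSums(Wc^2))
  r <- num / den
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(m - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  t_stat[r^2 >= 1 - 1e-14] <- sign(r[r^2 >= 1 - 1e-14]) * 1e8
  p <- 2 * pt(-abs(t_stat), df = m - 2)
  dimnames(t_stat) <- dimnames(p) <- list(rownames(mat), names(gene_sets))
  if (zscore) {
    mu <- colMeans(t_stat)
    sg <- apply(t_stat, 2L, sd)
    sg[sg == 0] <- 1
    t_stat <- sweep(sweep(t_stat, 2L, mu), 2L, sg, "/")
  }
  structure(list(scores = t_stat, pvalues = pmax(p, .Machine$double.xmin)),
            class = "activity_matrix")
}

#' Build the coordinated gene signature of one program
#'
#' Cell types are selected as the union of network-coordinated targets
#' (cross-validated R-squared at least `r2_coord`) and cell types where the
#' factor explains more than `var_thresh` of variance; if the factor's
#' explained variance is restricted to a single cell type, only that cell
#' type is used. Within the selected cell types, genes with |w| at least
#' `w_thresh` in at least one selected cell type are retained, with weight
#' equal to the mean of the retained (above-threshold) loadings. The
#' absolute threshold presumes loadings on an interpretable bounded scale;
#' for factorizations with unit-norm loading columns set `rescale = TRUE`
#' to rescale each (cell type, factor) column to max |w| = 1 first.
#'
#' @param model fitted `factor_model`.
#' @param net `dependency_network` fitted on the factor's activities.
#' @param factor factor id (column name of the model scores).
#' @param r2_coord coordination threshold on cross-validated R2.
#' @param var_thresh variance-explained threshold (strict).
#' @param w_thresh absolute-loading threshold.
#' @param rescale rescale loading columns to max |w| = 1 before
#'   thresholding (default FALSE).
#' @return Named numeric vector of signature gene weights (class
#'   `weighted_gene_set`, attribute `source`).
#' @export
coordinated_signature <- function(model, net, factor, r2_coord = 0.8,
                                  var_thresh = 0.10, w_thresh = 0.5,
                                  rescale = FALSE) {
  stopifnot(inherits(model, "factor_model"))
  r2f <- model$r2[model$r2$factor == factor & !is.na(model$r2$r2), ]
  varmax <- tapply(r2f$r2, r2f$celltype, max)
  var_cts <- names(varmax)[varmax > var_thresh]
  coord_cts <- if (!is.null(net)) {
    names(net$cv_r2)[net$cv_r2 >= r2_coord]
  } else character()
  cts <- if (length(var_cts) == 1L) var_cts else union(coord_cts, var_cts)
  cts <- intersect(cts, names(model$w))
  if (!length(cts)) .stopf("no cell types selected for factor '%s'", factor)
  wlist <- lapply(cts, function(ct) {
    w <- model$w[[ct]][, factor]
    if (rescale && max(abs(w)) > 0) w <- w / max(abs(w))
    w
  })
  names(wlist) <- cts
  genes <- unique(unlist(lapply(wlist, names)))
  keep <- vapply(genes, function(g) any(vapply(wlist, function(w)
    g %in% names(w) && abs(w[g]) >= w_thresh, logical(1))), logical(1))
  genes <- genes[keep]
  if (!length(genes)) .stopf("no genes pass |w| >= %g", w_thresh)
  weights <- vapply(genes, function(g) {
    vals <- unlist(lapply(wlist, function(w)
      if (g %in% names(w) && abs(w[g]) >= w_thresh) w[g] else NULL))
    mean(vals)
  }, numeric(1))
  structure(setNames(weights, genes), class = "weighted_gene_set",
            source = paste0(factor, "|", paste(cts, collapse = "+")),
            celltypes = cts)
}

#' Map multicellular programs onto bulk samples
#'
#' Scores each (factor, cell type) loading set on every bulk sample with the
#' ULM, then averages across cell types with weights proportional to the sum
#' over groups of the factor's variance explained in that cell type
#' (normalized to sum 1 per factor).
#'
#' @param bulk sample x gene matrix, z-scored to controls.
#' @param model fitted `factor_model`.
#' @param factors factor ids to map (default: all).
#' @return A list: `wmean` (sample x factor weighted scores), `per_celltype`
#'   (sample x (factor|celltype) ULM scores), `weights` used per factor.
#' @export
map_programs_bulk <- function(bulk, model, factors = NULL) {
  if (is.null(factors)) factors <- colnames(model$z_all)
  sets <- list(); wts <- list()
  for (f in factors) {
    r2f <- model$r2[model$r2$factor == f & !is.na(model$r2$r2), ]
    r2sum <- tapply(r2f$r2, r2f$celltype, sum)
    for (ct in names(model$w)) {
      w <- model$w[[ct]][, f]
      # loading gene names carry a view prefix in synthetic cohorts; match
      # against bulk universe as-is
      if (length(intersect(names(w), colnames(bulk))) >= 3L)
        sets[[paste0(f, "|", ct)]] <- w
    }
    wt <- r2sum[names(model$w)]
    wt[is.na(wt)] <- 0
    wts[[f]] <- wt
  }
  if (!length(sets)) .stopf("no loading genes present in bulk matrix")
  act <- score_activities(bulk, sets)
  wmean <- matrix(0, nrow(bulk), length(factors),
                  dimnames = list(rownames(bulk), factors))
  for (f in factors) {
    cols <- paste0(f, "|", names(model$w))
    present <- cols %in% colnames(act$scores)
    wt <- wts[[f]][present]
    if (sum(wt) == 0) wt <- rep(1, length(wt))
    wt <- wt / sum(wt)
    wmean[, f] <- act$scores[, cols[present], drop = FALSE] %*% wt
  }
  list(wmean = wmean, per_celltype = act$scores, weights = wts)
}

#' Score ligand-receptor interactions per sample
#'
#' For every (source cell type, ligand, receptor, target cell type)
#' quadruplet and sample, the interaction magnitude is the geometric mean of
#' ligand expression in the sender and receptor expression in the receiver,
#' gated on a minimum detection fraction (`expr_prop`) in both populations;
#' otherwise 0. Missing cell types in a sample yield missing scores.
#'
#' @param mean_expr named list (cell type) of sample x gene mean-expression
#'   matrices.
#' @param detect_frac named list of sample x gene detection-fraction
#'   matrices, aligned with `mean_expr`.
#' @param lr_resource data.frame with `ligand` and `receptor` columns.
#' @param expr_prop minimum detection fraction (default 0.1, inclusive).
#' @return A list of class `lr_table`: `rows` (quadruplet data.frame) and
#'   `scores` (row x sample matrix, >= 0, NA where a cell type is missing).
#' @export
score_ccc <- function(mean_expr, detect_frac, lr_resource, expr_prop = 0.1) {
  cts <- names(mean_expr)
  samples <- sort(unique(unlist(lapply(mean_expr, rownames))))
  rows <- list(); scores <- list()
  for (src in cts) for (tgt in cts) {
    for (i in seq_len(nrow(lr_resource))) {
      lig <- lr_resource$ligand[i]; rec <- lr_resource$receptor[i]
      if (!lig %in% colnames(mean_expr[[src]]) ||
          !rec %in% colnames(mean_expr[[tgt]])) next
      sc <- setNames(rep(NA_real_, length(samples)), samples)
      common <- intersect(rownames(mean_expr[[src]]),
                          rownames(mean_expr[[tgt]]))
      el <- mean_expr[[src]][common, lig]
      er <- mean_expr[[tgt]][common, rec]
      fl <- detect_frac[[src]][common, lig]
      fr <- detect_frac[[tgt]][common, rec]
      val <- sqrt(pmax(el, 0) * pmax(er, 0))
      val[fl < expr_prop | fr < expr_prop] <- 0
      sc[common] <- val
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, ligand = lig, receptor = rec, target = tgt,
        stringsAsFactors = FALSE)
      scores[[length(scores) + 1L]] <- sc
    }
  }
  rowdf <- do.call(rbind, rows)
  smat <- do.call(rbind, scores)
  rownames(smat) <- paste(rowdf$source, rowdf$ligand, rowdf$receptor,
                          rowdf$target, sep = "^")
  structure(list(rows = rowdf, scores = smat), class = "lr_table")
}

#' Filter ligand-receptor interactions into analysis-ready views
#'
#' Keeps LR rows nonzero in at least `lr_prop` of samples; keeps
#' (source, target) views with a median per-sample nonzero-interaction count
#' of at least `min_inter`, at least `min_lr` retained LR pairs, and at
#' least `min_samples` covered samples; fills missing values with zero; and
#' finally restricts to views whose (source, target) pair is an edge of the
#' supplied dependency network.
#'
#' @param tab `lr_table` from [score_ccc()].
#' @param lr_prop minimum fraction of samples with nonzero score per row.
#' @param min_inter minimum median per-sample nonzero interactions per view.
#' @param min_lr minimum LR pairs per view.
#' @param min_samples minimum covered samples per view.
#' @param net_edges data.frame with `source` and `target` columns, or `NULL`
#'   to skip the network restriction.
#' @return Filtered `lr_table` (missing scores zero-filled).
#' @export
filter_ccc_views <- function(tab, lr_prop = 0.3, min_inter = 20L,
                             min_lr = 20L, min_samples = 100L,
                             net_edges = NULL) {
  stopifnot(inherits(tab, "lr_table"))
  sc <- tab$scores
  n_s <- ncol(sc)
  nonzero <- !is.na(sc) & sc > 0
  keep_row <- rowSums(nonzero) / n_s >= lr_prop
  rows <- tab$rows[keep_row, , drop = FALSE]
  sc <- sc[keep_row, , drop = FALSE]
  nonzero <- nonzero[keep_row, , drop = FALSE]
  if (nrow(rows)) {
    viewkey <- paste(rows$source, rows$target, sep = "^")
    keep_view <- vapply(unique(viewkey), function(vk) {
      idx <- viewkey == vk
      med_inter <- median(colSums(nonzero[idx, , drop = FALSE]))
      covered <- sum(colSums(!is.na(sc[idx, , drop = FALSE])) > 0)
      med_inter >= min_inter && sum(idx) >= min_lr && covered >= min_samples
    }, logical(1))
    ok <- viewkey %in% unique(viewkey)[keep_view]
    if (!is.null(net_edges)) {
      edgekey <- paste(net_edges$source, net_edges$target, sep = "^")
      ok <- ok & viewkey %in% edgekey
    }
    rows <- rows[ok, , drop = FALSE]
    sc <- sc[ok, , drop = FALSE]
  }
  sc[is.na(sc)] <- 0
  if (!nrow(rows)) .warnf("no LR interactions survive filtering")
  structure(list(rows = rows, scores = sc), class = "lr_table")
}

#' Select program-associated ligand-receptor interactions
#'
#' Correlates each interaction's per-sample score with the program score;
#' interactions with Pearson r strictly greater than `r_min` and p below
#' `alpha` are flagged, and sender/receiver counts per cell type are
#' summarized over the flagged set.
#'
#' @param tab filtered `lr_table`.
#' @param program_scores named numeric vector of per-sample program scores.
#' @param r_min correlation threshold (strict).
#' @param alpha p-value threshold (strict).
#' @return A list: `table` (rows with `r`, `p`, `keep`), `summary`
#'   (cell type, n_as_sender, n_as_receiver over kept rows).
#' @export
correlate_ccc_program <- function(tab, program_scores, r_min = 0.3,
                                  alpha = 0.05) {
  stopifnot(inherits(tab, "lr_table"))
  common <- intersect(colnames(tab$scores), names(program_scores))
  ps <- program_scores[common]
  res <- tab$rows
  res$r <- NA_real_; res$p <- NA_real_
  drop <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    x <- tab$scores[i, common]
    if (sd(x) == 0) { drop[i] <- TRUE; next }
    ct <- cor.test(x, ps)
    res$r[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  res <- res[!drop, , drop = FALSE]
  res$keep <- res$r > r_min & res$p < alpha
  kept <- res[res$keep, , drop = FALSE]
  cts <- sort(unique(c(res$source, res$target)))
  summ <- data.frame(celltype = cts,
                     n_as_sender = vapply(cts, function(ct)
                       sum(kept$source == ct), integer(1)),
                     n_as_receiver = vapply(cts, function(ct)
                       sum(kept$target == ct), integer(1)),
                     stringsAsFactors = FALSE)
  list(table = res, summary = summ)
}
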