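#' Fit a deterministic multi-group, multi-view factor model
#'
#' Decomposes joint pseudobulk variation across cell-type views into latent
#' factors with gene loadings shared across groups and sample scores estimated
#' per group. Each view is standardized per gene (genes centred within each
#' group, then scaled to unit variance) and scaled to unit total variance, so
#' no view dominates. Factors come from a truncated SVD of the
#' column-concatenated views; group scores are the least-squares projections
#' onto the shared loadings. Factors whose incremental explained variance
#' falls below `drop_r2` are dropped. Missing (cell type, sample) rows are
#' treated as absent observations: they are excluded from that view's
#' least-squares, never zero-imputed.
#'
#' Factor signs are made canonical: the gene with the largest absolute
#' loading is positive.
#'
#' @param views named list of sample x gene matrices (QC'd and gene-selected).
#' @param groups named character vector mapping sample id to group.
#' @param n_factors maximum number of factors (default 20).
#' @param drop_r2 incremental explained-variance threshold below which
#'   factors are dropped (default 0.001).
#' @return An object of class `factor_model` with loadings `w` (per cell
#'   type, gene x factor), scores `z` (per group, sample x factor), a pooled
#'   score matrix `z_all`, the variance-explained table `r2`, `view_scale`,
#'   and `n_factors`.
#' @export
fit_factors <- function(views, groups, n_factors = 20, drop_r2 = 0.001) {
  stopifnot(is.list(views), length(views) >= 1L)
  all_samples <- sort(unique(unlist(lapply(views, rownames))))
  if (is.null(names(groups))) .stopf("groups must be named by sample id")
  if (!all(all_samples %in% names(groups)))
    .stopf("every sample must have a group label")
  groups <- groups[all_samples]

  # per-view standardization: centre per gene within group, unit gene
  # variance, then unit total view variance
  std_views <- list()
  for (ct in names(views)) {
    v <- views[[ct]]
    g <- groups[rownames(v)]
    keep <- rep(TRUE, nrow(v))
    for (gr in unique(g)) {
      if (sum(g == gr) < 2L) {
        .warnf("view '%s': group '%s' has <2 samples, excluded", ct, gr)
        keep[g == gr] <- FALSE
      }
    }
    v <- v[keep, , drop = FALSE]
    g <- g[keep]
    for (gr in unique(g)) {
      idx <- which(g == gr)
      v[idx, ] <- sweep(v[idx, , drop = FALSE], 2L,
                        colMeans(v[idx, , drop = FALSE]))
    }
    sds <- apply(v, 2L, sd)
    sds[sds == 0 | is.na(sds)] <- 1
    v <- sweep(v, 2L, sds, "/")
    scale_ct <- sqrt(sum(apply(v, 2L, var), na.rm = TRUE))
    if (scale_ct == 0) scale_ct <- 1
    std_views[[ct]] <- v / scale_ct
  }
  view_scale <- vapply(std_views, function(v) 1, numeric(1))

  gene_offsets <- c(0, cumsum(vapply(std_views, ncol, integer(1))))
  X <- matrix(NA_real_, length(all_samples), gene_offsets[length(std_views) + 1L],
              dimnames = list(all_samples, NULL))
  cn <- character(ncol(X))
  for (i in seq_along(std_views)) {
    cols <- (gene_offsets[i] + 1L):gene_offsets[i + 1L]
    v <- std_views[[i]]
    X[rownames(v), cols] <- v
    cn[cols] <- paste0(names(std_views)[i], ".", colnames(v))
  }
  colnames(X) <- cn

  obs <- !is.na(X)
  Xf <- X
  Xf[!obs] <- 0
  k <- min(n_factors, nrow(X) - 1L, ncol(X))
  sv <- svd(Xf, nu = k, nv = k)
  if (any(!obs)) {
    for (it in 1:5) {
      rec <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
      Xf[!obs] <- rec[!obs]
      sv <- svd(Xf, nu = k, nv = k)
    }
  }
  tot_ss <- sum(X[obs]^2)
  inc <- sv$d[seq_len(k)]^2 / tot_ss
  keep_f <- which(inc >= drop_r2)
  if (!length(keep_f)) keep_f <- 1L
  k <- max(keep_f)
  V <- sv$v[, seq_len(k), drop = FALSE]
  fnames <- paste0("Factor", seq_len(k))
  rownames(V) <- cn
  colnames(V) <- fnames

  # canonical sign: largest |loading| gene positive
  for (f in seq_len(k)) {
    j <- which.max(abs(V[, f]))
    if (V[j, f] < 0) V[, f] <- -V[, f]
  }

  # group-wise scores: least squares against shared loadings over the
  # columns observed for each sample
  Z <- matrix(NA_real_, nrow(X), k, dimnames = list(all_samples, fnames))
  complete <- rowSums(!obs) == 0L
  if (any(complete))
    Z[complete, ] <- X[complete, , drop = FALSE] %*% V
  for (s in which(!complete)) {
    oc <- obs[s, ]
    Vo <- V[oc, , drop = FALSE]
    Z[s, ] <- qr.solve(crossprod(Vo), crossprod(Vo, X[s, oc]))
  }

  w <- list()
  for (i in seq_along(std_views)) {
    cols <- (gene_offsets[i] + 1L):gene_offsets[i + 1L]
    wi <- V[cols, , drop = FALSE]
    rownames(wi) <- colnames(std_views[[i]])
    w[[names(std_views)[i]]] <- wi
  }
  z <- lapply(split(all_samples, groups[all_samples]), function(ss)
    Z[ss, , drop = FALSE])

  model <- structure(list(w = w, z = z, z_all = Z, view_scale = view_scale,
                          n_factors = k, groups = groups,
                          std_views = std_views, r2 = NULL),
                     class = "factor_model")
  model$r2 <- variance_explained(model)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors, %d views, %d samples, %d groups\n",
              x$n_factors, length(x$w), nrow(x$z_all), length(x$z)))
  invisible(x)
}

#' Per-(group, cell type, factor) variance explained
#'
#' For each factor the fraction of a view's within-group variance captured by
#' its rank-1 reconstruction, `1 - SS_res / SS_tot`, on the fit's
#' standardized scale, clipped at 0. Zero-variance (group, view) blocks are
#' reported as `NA`.
#'
#' @param model a fitted `factor_model`.
#' @param views ignored; the model retains its standardized views.
#' @return Long data.frame with columns `group`, `celltype`, `factor`, `r2`.
#' @export
variance_explained <- function(model, views = NULL) {
  stopifnot(inherits(model, "factor_model"))
  out <- list()
  fnames <- colnames(model$z_all)
  for (ct in names(model$std_views)) {
    v <- model$std_views[[ct]]
    g <- model$groups[rownames(v)]
    for (gr in unique(g)) {
      Xg <- v[g == gr, , drop = FALSE]
      zg <- model$z_all[rownames(Xg), , drop = FALSE]
      ss_tot <- sum(Xg^2)
      for (f in seq_along(fnames)) {
        r2 <- if (ss_tot == 0) NA_real_ else {
          res <- Xg - zg[, f] %*% t(model$w[[ct]][, f])
          max(0, 1 - sum(res^2) / ss_tot)
        }
        out[[length(out) + 1L]] <- data.frame(
          group = gr, celltype = ct, factor = fnames[f], r2 = r2,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Select disease-relevant programs by variance explained
#'
#' A factor is selected iff it explains strictly more than `threshold` of the
#' variance in at least one (cell type, group) block.
#'
#' @param r2 long-format variance-explained table (see
#'   [variance_explained()]).
#' @param threshold strict variance-explained cutoff (default 0.10).
#' @return Character vector of selected factor ids.
#' @export
select_programs <- function(r2, threshold = 0.10) {
  if (is.null(r2) || nrow(r2) == 0L) return(character())
  sel <- stats::aggregate(r2 ~ factor, data = r2[!is.na(r2$r2), ], FUN = max)
  sel$factor[sel$r2 > threshold]
}

#' Associate factor scores with clinical covariates
#'
#' Per covariate, a multivariate linear model of the covariate on all factor
#' scores gives a global R-squared (for categorical covariates, a redundancy
#' index over indicator columns). Per (factor, covariate) pair, a univariate
#' model gives the ANOVA F-test p-value, eta-squared, and the slope
#' t-statistic for direction; p-values are Bonferroni-adjusted across factors
#' within each covariate.
#'
#' @param scores sample x factor score matrix.
#' @param covariates data.frame aligned to the score rows.
#' @return A list of class `covariate_association`: `global` (covariate,
#'   r2) and `pairs` (factor, covariate, F, p, eta2, t, p_adjusted).
#' @export
associate_covariates <- function(scores, covariates) {
  stopifnot(nrow(scores) == nrow(covariates))
  fnames <- colnames(scores)
  glob <- list(); pairs <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      .warnf("covariate '%s' is constant; skipped", cv)
      next
    }
    Y <- if (is.numeric(x)) matrix(x, ncol = 1L) else {
      mm <- model.matrix(~ factor(x) - 1)
      mm[, -1L, drop = FALSE]  # drop one level; R2 invariant to reference
    }
    ssr <- sstot <- 0
    for (j in seq_len(ncol(Y))) {
      fitj <- lm(Y[, j] ~ scores)
      sstot <- sstot + sum((Y[, j] - mean(Y[, j]))^2)
      ssr <- ssr + sum(resid(fitj)^2)
    }
    glob[[cv]] <- data.frame(covariate = cv, r2 = 1 - ssr / sstot,
                             stringsAsFactors = FALSE)

    pv <- data.frame(factor = fnames, covariate = cv, F = NA_real_,
                     p = NA_real_, eta2 = NA_real_, t = NA_real_,
                     stringsAsFactors = FALSE)
    for (f in seq_along(fnames)) {
      xx <- if (is.numeric(x)) x else factor(x)
      fit <- lm(scores[, f] ~ xx)
      an <- anova(fit)
      pv$F[f] <- an$`F value`[1L]
      pv$p[f] <- an$`Pr(>F)`[1L]
      pv$eta2[f] <- an$`Sum Sq`[1L] / sum(an$`Sum Sq`)
      pv$t[f] <- summary(fit)$coefficients[2L, "t value"]
    }
    pv$p_adjusted <- pmin(1, pv$p * length(fnames))
    pairs[[cv]] <- pv
  }
  structure(list(global = do.call(rbind, glob),
                 pairs = do.call(rbind, pairs)),
            class = "covariate_association")
}
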