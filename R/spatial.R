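#' Binary k-nearest-neighbour spatial weight matrix
#'
#' `W[i, j] = 1` iff spot j is among the k nearest neighbours of spot i
#' (Euclidean distance); distance ties are broken in favour of the lower
#' spot index. The diagonal is zero and every row sums to k.
#'
#' @param coords spot x 2 coordinate matrix.
#' @param k number of neighbours (default 6).
#' @return A list of class `spatial_weights`: `W` (binary matrix), `k`,
#'   `S0` (total weight, `n * k`).
#' @export
knn_weights <- function(coords, k = 6L) {
  n <- nrow(coords)
  if (n <= k) .stopf("need more spots than k")
  D <- as.matrix(dist(coords))
  W <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]  # ties: lowest index first
    W[i, nb] <- 1
  }
  structure(list(W = W, k = k, S0 = sum(W)), class = "spatial_weights")
}

#' Bivariate global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#' sqrt(sum (x - xbar)^2 * sum (y - ybar)^2)`. With `x == y` this reduces
#' exactly to the univariate global Moran's I.
#'
#' @param x,y numeric spot vectors with positive variance.
#' @param W a `spatial_weights` object or raw weight matrix.
#' @return The Moran's I statistic.
#' @export
bivariate_moran <- function(x, y, W) {
  if (inherits(W, "spatial_weights")) { S0 <- W$S0; W <- W$W }
  else S0 <- sum(W)
  if (var(x) == 0 || var(y) == 0) .stopf("zero variance input")
  n <- length(x)
  zx <- x - mean(x)
  zy <- y - mean(y)
  (n / S0) * drop(zx %*% W %*% zy) / sqrt(sum(zx^2) * sum(zy^2))
}

#' Permutation p-value for bivariate Moran's I
#'
#' Permutes `y` over spots and computes the two-tailed p-value in the
#' Davison-Hinkley small-sample form, `p = (1 + #{|I*| >= |I_obs|}) /
#' (n_perms + 1)`; the minimum achievable p is `1 / (n_perms + 1)`.
#'
#' @param x,y spot vectors.
#' @param W `spatial_weights` or weight matrix.
#' @param n_perms number of permutations (default 100).
#' @param seed integer seed.
#' @return A list: `I` (observed), `p` (two-tailed permutation p).
#' @export
moran_permutation_p <- function(x, y, W, n_perms = 100L, seed = 1L) {
  I_obs <- bivariate_moran(x, y, W)
  Istar <- .with_seed(seed, vapply(seq_len(n_perms), function(i)
    bivariate_moran(x, sample(y), W), numeric(1)))
  list(I = I_obs, p = (1 + sum(abs(Istar) >= abs(I_obs))) / (n_perms + 1))
}

#' Combine per-slide co-localization evidence
#'
#' Within each (cell type, program, condition) cell, averages per-slide
#' Moran's I and combines the per-slide permutation p-values with Fisher's
#' method (chi-squared with 2k degrees of freedom, k = number of slides).
#' Combined p-values are BH-adjusted across all cells; a cell is significant
#' iff fdr < 0.05 and |mean I| >= 0.10.
#'
#' @param per_slide data.frame with columns `celltype`, `program`,
#'   `condition`, `slide`, `I`, `p`.
#' @return data.frame per (celltype, program, condition): `mean_I`,
#'   `n_slides`, `fisher_stat`, `p_combined`, `fdr`, `significant`.
#' @export
aggregate_colocalization <- function(per_slide) {
  key <- interaction(per_slide$celltype, per_slide$program,
                     per_slide$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_slide, key), function(d) {
    stat <- -2 * sum(log(d$p))
    data.frame(celltype = d$celltype[1L], program = d$program[1L],
               condition = d$condition[1L], mean_I = mean(d$I),
               n_slides = nrow(d), fisher_stat = stat,
               p_combined = pchisq(stat, df = 2 * nrow(d),
                                   lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p_combined, method = "BH")
  out$significant <- out$fdr < 0.05 & abs(out$mean_I) >= 0.10
  out
}

# mode of the per-spot minimum-distance distribution (nearest-neighbor
# spacing), on values rounded to 6 digits
.nn_spacing <- function(coords) {
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  mins <- round(apply(D, 1L, min), 6L)
  as.numeric(names(sort(table(mins), decreasing = TRUE))[1L])
}

#' Build intra- and para-views for neighbourhood modelling
#'
#' Compositions below `zero_thresh` are zeroed, zero-variance cell types
#' dropped, and the rest CLR-transformed after adding `pseudocount`. The
#' paraview is the distance-weighted mean of neighbouring spots within
#' radius `r = l * spacing` (spacing = mode of per-spot nearest-neighbour
#' distances), with a Gaussian kernel of bandwidth `r / 2` and the spot
#' itself excluded; isolated spots get a zero row and a flag. The mask
#' covers glomerular spots and neighbours within two spot spacings.
#'
#' @param compositions spot x celltype proportions (rows sum to <= 1).
#' @param coords spot x 2 coordinates.
#' @param glomerular logical per-spot annotation.
#' @param zero_thresh compositions below this are set to 0 (default 0.05).
#' @param pseudocount added before the log (default 1e-31).
#' @param l radius multiplier (default 2).
#' @return A list: `intraview` (CLR spot x celltype), `paraview`, `mask`
#'   (logical), `isolated` (logical), `radius`, `spacing`.
#' @export
build_views <- function(compositions, coords, glomerular,
                        zero_thresh = 0.05, pseudocount = 1e-31, l = 2) {
  if (!any(glomerular)) .stopf("no glomerular annotation: mask empty")
  comp <- as.matrix(compositions)
  comp[comp < zero_thresh] <- 0
  keep <- apply(comp, 2L, var) > 0
  comp <- comp[, keep, drop = FALSE]
  lp <- log(comp + pseudocount)
  intra <- lp - rowMeans(lp)

  spacing <- .nn_spacing(coords)
  r <- l * spacing
  bw <- r / 2
  D <- as.matrix(dist(coords))
  K <- exp(-D^2 / (2 * bw^2))
  K[D > r] <- 0
  diag(K) <- 0
  tot <- rowSums(K)
  isolated <- tot == 0
  para <- matrix(0, nrow(intra), ncol(intra), dimnames = dimnames(intra))
  nz <- !isolated
  para[nz, ] <- (K[nz, , drop = FALSE] %*% intra) / tot[nz]

  dglom <- apply(D[, glomerular, drop = FALSE], 1L, min)
  mask <- glomerular | dglom <= 2 * spacing
  list(intraview = intra, paraview = para, mask = mask,
       isolated = isolated, radius = r, spacing = spacing)
}

#' Multi-view neighbourhood model of a target cell type
#'
#' Predicts the target's intraview signal from (i) the other intraview
#' features and (ii) the paraview features, using a pluggable learner
#' (random forest by default), on the masked spots. Reports per-predictor
#' importances per view and fractional view contributions from an
#' R-squared-gain attribution: the intraview contributes its own
#' out-of-bag R2, the paraview the gain of the combined model over the
#' intraview model (both floored at 0, normalized to sum 1).
#'
#' @param views output of [build_views()].
#' @param target cell-type column name to predict.
#' @param learner `"random_forest"` or `"linear"`.
#' @param seed integer seed (forests are fitted single-threaded for
#'   reproducibility).
#' @return A list: `importances` (named list per view), `r2`
#'   (intra, combined), `contributions` (fractions per view).
#' @export
fit_multiview <- function(views, target, learner = "random_forest",
                          seed = 1L) {
  mask <- views$mask
  if (sum(mask) < 20L) .stopf("fewer than 20 masked spots")
  ord <- order(rownames(views$intraview))  # spot-order invariance
  intra <- views$intraview[ord, , drop = FALSE][mask[ord], , drop = FALSE]
  y <- intra[, target]
  Xi <- intra[, setdiff(colnames(intra), target), drop = FALSE]
  Xp <- views$paraview[ord, , drop = FALSE][mask[ord], , drop = FALSE]
  colnames(Xp) <- paste0("para_", colnames(Xp))

  fit_one <- function(X) {
    if (learner == "random_forest") {
      d <- data.frame(y = y, X, check.names = FALSE)
      rf <- ranger::ranger(y ~ ., data = d, seed = seed,
                           num.threads = 1L, importance = "impurity",
                           num.trees = 300L)
      list(r2 = rf$r.squared, importance = rf$variable.importance)
    } else {
      fit <- lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
      pr <- fitted(fit)
      imp <- abs(coef(fit)[-1L]) * apply(X, 2L, sd)
      list(r2 = 1 - sum((y - pr)^2) / sum((y - mean(y))^2),
           importance = imp)
    }
  }
  fi <- fit_one(Xi)
  fc <- fit_one(cbind(Xi, Xp))
  r2_intra <- max(fi$r2, 0)
  gain_para <- max(fc$r2 - fi$r2, 0)
  tot <- r2_intra + gain_para
  contributions <- if (tot > 0) c(intra = r2_intra, para = gain_para) / tot
    else c(intra = 0, para = 0)
  imp_para <- fc$importance[grepl("^para_", names(fc$importance))]
  list(importances = list(intra = fi$importance, para = imp_para),
       r2 = c(intra = fi$r2, combined = fc$r2),
       contributions = contributions)
}

#' Program enrichment in glomerular spots
#'
#' Restricts to glomerular spots with nonzero immune composition, then per
#' program fits an ordinary linear model of the spot-level enrichment score
#' on the condition indicator (case vs control); positive t means enriched
#' in cases. Also returns visualization-ready scores with negative
#' enrichment clamped to zero.
#'
#' @param scores spot x program enrichment matrix.
#' @param glomerular logical per-spot mask.
#' @param immune numeric per-spot immune composition (spots with 0 removed).
#' @param condition character per spot, `"case"` / `"control"`.
#' @return A list: `tests` (program, t, p), `vis_scores` (clamped matrix on
#'   the tested spots).
#' @export
glomerular_enrichment <- function(scores, glomerular, immune, condition) {
  sel <- glomerular & immune > 0
  cond <- condition[sel]
  if (length(unique(cond)) < 2L) .stopf("both conditions required")
  sub <- scores[sel, , drop = FALSE]
  ind <- as.numeric(cond == "case")
  tests <- do.call(rbind, lapply(colnames(sub), function(pr) {
    fit <- summary(lm(sub[, pr] ~ ind))
    data.frame(program = pr, t = fit$coefficients[2L, "t value"],
               p = fit$coefficients[2L, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }))
  list(tests = tests, vis_scores = pmax(sub, 0))
}
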