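#' Fit a directed cell-type dependency network
#'
#' One ridge regression per target cell type predicts its per-sample program
#' activity from the activities of all other cell types. The ridge penalty is
#' chosen per target by generalized cross-validation over a fixed grid;
#' `cv_r2` is the mean held-out R-squared over 5 folds at the chosen penalty
#' (fold assignment is seeded and based on sorted sample ids, so it is
#' invariant to input row order); `beta` comes from a final fit on all masked
#' samples.
#'
#' @param activities sample x celltype matrix of z-scored program activities.
#' @param mask logical or character vector selecting the samples to fit on
#'   (default all).
#' @param penalty_grid ridge penalties searched (default 10^(-2:2)).
#' @param nfolds cross-validation folds (default 5).
#' @param fold_seed integer seed for fold assignment.
#' @param condition label stored on the network (`"all"`, `"case"`,
#'   `"control"`).
#' @return An object of class `dependency_network`: `celltypes`, `beta`
#'   (source x target, zero diagonal), `cv_r2`, `penalty` (per target),
#'   `condition`.
#' @export
fit_dependency_network <- function(activities, mask = NULL,
                                   penalty_grid = 10^(-2:2), nfolds = 5L,
                                   fold_seed = 1L, condition = "all") {
  if (is.null(mask)) mask <- rep(TRUE, nrow(activities))
  X <- activities[mask, , drop = FALSE]
  if (nrow(X) < 10L) .stopf("need >= 10 samples to fit the network")
  if (any(apply(X, 2L, sd) == 0)) .stopf("constant activity column")
  cts <- colnames(X)
  n <- nrow(X)
  ord <- order(rownames(X))
  folds <- .with_seed(fold_seed,
                      sample(rep(seq_len(nfolds), length.out = n)))
  fold_of <- integer(n)
  fold_of[ord] <- folds  # assigned along sorted sample ids

  ridge_beta <- function(Xp, y, lambda) {
    p <- ncol(Xp)
    xm <- colMeans(Xp); ym <- mean(y)
    Xc <- sweep(Xp, 2L, xm)
    yc <- y - ym
    b <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, yc))
    list(beta = drop(b), intercept = ym - sum(xm * b))
  }

  beta <- matrix(0, length(cts), length(cts), dimnames = list(cts, cts))
  cv_r2 <- setNames(numeric(length(cts)), cts)
  penalty <- setNames(numeric(length(cts)), cts)
  for (tgt in cts) {
    y <- X[, tgt]
    Xp <- X[, setdiff(cts, tgt), drop = FALSE]
    # generalized cross-validation on the full masked set
    gcv <- vapply(penalty_grid, function(lam) {
      Xc <- sweep(Xp, 2L, colMeans(Xp))
      H <- Xc %*% solve(crossprod(Xc) + lam * diag(ncol(Xc)), t(Xc))
      df <- sum(diag(H)) + 1
      fitv <- H %*% (y - mean(y)) + mean(y)
      n * sum((y - fitv)^2) / (n - df)^2
    }, numeric(1))
    lam <- penalty_grid[which.min(gcv)]
    penalty[tgt] <- lam
    # 5-fold held-out R2 at the chosen penalty
    r2s <- vapply(seq_len(nfolds), function(fd) {
      tr <- fold_of != fd
      fit <- ridge_beta(Xp[tr, , drop = FALSE], y[tr], lam)
      pred <- Xp[!tr, , drop = FALSE] %*% fit$beta + fit$intercept
      1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[tr]))^2)
    }, numeric(1))
    cv_r2[tgt] <- mean(r2s)
    fit <- ridge_beta(Xp, y, lam)
    beta[setdiff(cts, tgt), tgt] <- fit$beta
  }
  structure(list(celltypes = cts, beta = beta, cv_r2 = cv_r2,
                 penalty = penalty, condition = condition),
            class = "dependency_network")
}

#' @export
print.dependency_network <- function(x, ...) {
  cat(sprintf("dependency_network (%s): %d cell types, mean CV R2 = %.3f\n",
              x$condition, length(x$celltypes), mean(x$cv_r2)))
  invisible(x)
}

#' Classify condition-specific dependency edges
#'
#' An ordered (source, target) pair is `shared` when the two condition
#' coefficients have opposite signs or differ in magnitude by less than
#' `tol`; otherwise it is `HC_enriched` when the control coefficient is the
#' larger and `SLE_enriched` when the case coefficient is. `sign(0)` counts
#' as positive. A boundary difference `|delta| == tol` is classified (only
#' strictly smaller differences are shared).
#'
#' @param net_hc,net_sle `dependency_network` objects on the same cell
#'   types (control and case).
#' @param tol magnitude threshold (default 0.1).
#' @return data.frame with `source`, `target`, `beta_hc`, `beta_sle`,
#'   `delta` (case minus control) and `class`.
#' @export
classify_edges <- function(net_hc, net_sle, tol = 0.1) {
  stopifnot(identical(net_hc$celltypes, net_sle$celltypes))
  cts <- net_hc$celltypes
  out <- list()
  sgn <- function(x) ifelse(x >= 0, 1, -1)
  for (src in cts) for (tgt in cts) {
    if (src == tgt) next
    bh <- net_hc$beta[src, tgt]; bs <- net_sle$beta[src, tgt]
    cls <- if (sgn(bh) != sgn(bs) || abs(bh - bs) < tol) "shared"
      else if (bh > bs) "HC_enriched" else "SLE_enriched"
    out[[length(out) + 1L]] <- data.frame(
      source = src, target = tgt, beta_hc = bh, beta_sle = bs,
      delta = bs - bh, class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Edge list of a dependency network for downstream restriction
#'
#' An edge is present when the coefficient magnitude in the all-sample
#' network exceeds `threshold` (the default convention for restricting
#' cell-cell communication views).
#'
#' @param net a `dependency_network`.
#' @param threshold absolute-coefficient cutoff (default 0.1).
#' @return data.frame with `source` and `target` columns.
#' @export
network_edges <- function(net, threshold = 0.1) {
  idx <- which(abs(net$beta) > threshold, arr.ind = TRUE)
  data.frame(source = rownames(net$beta)[idx[, 1L]],
             target = colnames(net$beta)[idx[, 2L]],
             beta = net$beta[idx], stringsAsFactors = FALSE)
}
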