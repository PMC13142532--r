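#' Fit archetypes by alternating simplex-constrained least squares
#'
#' Minimizes `||X - S A||^2` where the mixture rows of `S` lie on the
#' probability simplex and the archetypes `A = B X` are themselves convex
#' combinations of the data (rows of `B` on the simplex), the principal
#' convex hull formulation. Both blocks are updated by projected gradient
#' with backtracking from a furthest-point initialization, so the residual
#' sum of squares is non-increasing across iterations by construction.
#'
#' @param embedding cell x dim coordinate matrix.
#' @param k number of archetypes (>= 2).
#' @param max_iter maximum outer iterations.
#' @param inner inner projected-gradient steps per block.
#' @param tol relative RSS improvement below which iteration stops.
#' @return An object of class `archetype_model`: `embedding`, `A` (k x dim),
#'   `S` (cell x k), `B`, `rss`, `rss_path`, `k`, `lengthscale` (half the
#'   median centroid-to-archetype distance), `converged`.
#' @export
fit_archetypes <- function(embedding, k, max_iter = 60L, inner = 8L,
                           tol = 1e-9) {
  if (k < 2) .stopf("k must be >= 2")
  X <- as.matrix(embedding)
  n <- nrow(X)
  if (n < 10 * k)
    .warnf("fewer than 10*k cells; archetypes may be unstable")

  # furthest-point initialization
  centroid <- colMeans(X)
  d0 <- sqrt(rowSums(sweep(X, 2L, centroid)^2))
  idx <- which.max(d0)
  for (i in seq_len(k - 1L)) {
    dmin <- apply(X[idx, , drop = FALSE], 1L, function(a)
      rowSums(sweep(X, 2L, a)^2))
    dmin <- if (is.matrix(dmin)) apply(dmin, 1L, min) else dmin
    cand <- which.max(dmin)
    idx <- c(idx, cand)
  }
  B <- matrix(0, k, n)
  B[cbind(seq_len(k), idx)] <- 1
  A <- B %*% X
  S <- matrix(1 / k, n, k)

  rss_of <- function(S, A) sum((X - S %*% A)^2)

  step_S <- 1; step_B <- 1
  update_S <- function(S, A, f_cur) {
    AAt <- A %*% t(A)
    L <- 2 * max(abs(eigen(AAt, symmetric = TRUE,
                           only.values = TRUE)$values))
    st <- min(step_S, 1 / max(L, 1e-12))
    for (it in seq_len(inner)) {
      G <- 2 * (S %*% AAt - X %*% t(A))
      repeat {
        Snew <- .project_simplex_rows(S - st * G)
        f_new <- rss_of(Snew, A)
        if (f_new <= f_cur + 1e-12) break
        st <- st / 2
        if (st < 1e-14) { Snew <- S; f_new <- f_cur; break }
      }
      S <- Snew; f_cur <- f_new; st <- st * 1.2
    }
    step_S <<- st
    list(S = S, f = f_cur)
  }
  update_B <- function(B, S, f_cur) {
    StS <- crossprod(S)
    StX <- crossprod(S, X)
    L <- 2 * max(abs(eigen(StS, symmetric = TRUE,
                           only.values = TRUE)$values)) *
      max(colSums(X^2))
    st <- min(step_B, 1 / max(L, 1e-12))
    for (it in seq_len(inner)) {
      G <- 2 * (StS %*% (B %*% X) - StX) %*% t(X)
      repeat {
        Bnew <- .project_simplex_rows(B - st * G)
        f_new <- rss_of(S, Bnew %*% X)
        if (f_new <= f_cur + 1e-12) break
        st <- st / 2
        if (st < 1e-16) { Bnew <- B; f_new <- f_cur; break }
      }
      B <- Bnew; f_cur <- f_new; st <- st * 1.2
    }
    step_B <<- st
    list(B = B, f = f_cur)
  }

  f <- rss_of(S, A)
  rss_path <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    up <- update_S(S, A, f); S <- up$S; f <- up$f
    ub <- update_B(B, S, f); B <- ub$B; f <- ub$f
    A <- B %*% X
    rss_path <- c(rss_path, f)
    if (iter > 1L) {
      prev <- rss_path[iter - 1L]
      if ((prev - f) <= tol * max(prev, 1e-12)) { converged <- TRUE; break }
    }
  }
  rownames(A) <- paste0("arch", seq_len(k))
  colnames(S) <- rownames(A)
  ls <- 0.5 * median(sqrt(rowSums(sweep(A, 2L, colMeans(X))^2)))
  structure(list(embedding = X, A = A, S = S, B = B, rss = f,
                 rss_path = rss_path, k = k, lengthscale = ls,
                 converged = converged, stability = NULL),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("archetype_model: k = %d, %d cells, RSS = %.4g%s\n",
              x$k, nrow(x$S), x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Scan a range of archetype numbers
#'
#' Fits archetypes for each k in `k_range` and reports RSS together with an
#' elbow-style information criterion (the second difference of RSS); the
#' suggested k maximizes the criterion.
#'
#' @param embedding cell x dim matrix.
#' @param k_range integer vector of candidate k.
#' @param ... passed to [fit_archetypes()].
#' @return A list: `table` (k, rss, ic) and `best_k`.
#' @export
select_k_archetypes <- function(embedding, k_range, ...) {
  fits <- lapply(k_range, function(k) fit_archetypes(embedding, k, ...))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  ic <- rep(NA_real_, length(k_range))
  if (length(k_range) >= 3L)
    for (i in 2:(length(k_range) - 1L))
      ic[i] <- rss[i - 1L] - 2 * rss[i] + rss[i + 1L]
  best <- if (all(is.na(ic))) k_range[which.min(rss)] else
    k_range[which.max(ic)]
  list(table = data.frame(k = k_range, rss = rss, ic = ic),
       best_k = best, fits = fits)
}

#' Bootstrap stability of fitted archetypes
#'
#' Refits the model on bootstrap resamples of the cells and reports, per
#' reference archetype, the mean best-match agreement (cosine similarity of
#' centroid-centered coordinates after optimal matching, clipped to [0, 1]).
#'
#' @param model fitted `archetype_model`.
#' @param n_boot number of resamplings (default 50).
#' @param seed integer seed.
#' @param ... passed to [fit_archetypes()].
#' @return Numeric vector of per-archetype stabilities in [0, 1].
#' @export
bootstrap_stability <- function(model, n_boot = 50L, seed = 1L, ...) {
  X <- model$embedding
  centroid <- colMeans(X)
  Aref <- sweep(model$A, 2L, centroid)
  .with_seed(seed, {
    agree <- matrix(0, n_boot, model$k)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(X), replace = TRUE)
      fit <- fit_archetypes(X[rows, , drop = FALSE], model$k, ...)
      Ab <- sweep(fit$A, 2L, centroid)
      perm <- .match_rows(Aref, Ab)
      for (i in seq_len(model$k)) {
        u <- Aref[i, ]; v <- Ab[perm[i], ]
        den <- sqrt(sum(u^2)) * sqrt(sum(v^2))
        agree[b, i] <- if (den == 0) 0 else max(0, sum(u * v) / den)
      }
    }
    colMeans(agree)
  })
}

#' Radial-basis-function cell weights for each archetype
#'
#' `w_ic = exp(-d(x_i, a_c)^2 / (2 l^2))` with length scale `l` equal to
#' one-half of the median distance from the data centroid to the archetypes
#' (stored on the model).
#'
#' @param model fitted `archetype_model`.
#' @return cell x k weight matrix with entries in (0, 1].
#' @export
rbf_weights <- function(model) {
  l <- model$lengthscale
  if (l <= 0) .stopf("length scale is 0 (all archetypes at the centroid)")
  D2 <- outer(rowSums(model$embedding^2), rowSums(model$A^2), "+") -
    2 * model$embedding %*% t(model$A)
  D2 <- pmax(D2, 0)
  W <- exp(-D2 / (2 * l^2))
  dimnames(W) <- list(rownames(model$embedding), rownames(model$A))
  W
}

#' Archetype expression profiles as weight-normalized means
#'
#' `profile_c = sum_i w_ic z_i / sum_i w_ic` over cells, for a z-scored
#' expression matrix aligned with the weight rows.
#'
#' @param weights cell x k RBF weights.
#' @param zmat cell x gene z-scored expression.
#' @return k x gene profile matrix.
#' @export
archetype_profiles <- function(weights, zmat) {
  stopifnot(nrow(weights) == nrow(zmat))
  tot <- colSums(weights)
  if (any(tot == 0)) .stopf("archetype with zero total weight")
  P <- t(weights) %*% zmat / tot
  rownames(P) <- colnames(weights)
  P
}

#' Project patient mean states onto the archetype convex hull
#'
#' Solves, for every patient mean `p`, `min_s ||t(A) s - p||^2` subject to
#' `s >= 0, sum(s) = 1` by exact active-set enumeration (ties broken by
#' minimal-norm `s`). The deviation is the residual norm and is 0 iff the
#' mean lies inside the hull.
#'
#' @param patient_means patient x dim matrix.
#' @param A k x dim archetype coordinates.
#' @return A list: `projected` (patient x dim), `deviation` (>= 0),
#'   `mixtures` (patient x k simplex rows), `distances` (patient x k
#'   Euclidean distances to each archetype).
#' @export
project_patient_means <- function(patient_means, A) {
  P <- as.matrix(patient_means)
  k <- nrow(A)
  S <- t(apply(P, 1L, function(p) .simplex_lsq(A, p)))
  if (k == 1L) S <- matrix(S, ncol = 1L)
  proj <- S %*% A
  dev <- sqrt(rowSums((proj - P)^2))
  D <- sqrt(pmax(outer(rowSums(P^2), rowSums(A^2), "+") -
                   2 * P %*% t(A), 0))
  dimnames(D) <- list(rownames(P), rownames(A))
  dimnames(S) <- dimnames(D)
  list(projected = proj, deviation = dev, mixtures = S, distances = D)
}

# HC3 covariance of an OLS fit: (X'X)^-1 X' diag(e^2/(1-h)^2) X (X'X)^-1
.hc3_se <- function(Xd, y) {
  XtXi <- solve(crossprod(Xd))
  b <- XtXi %*% crossprod(Xd, y)
  e <- y - Xd %*% b
  h <- rowSums((Xd %*% XtXi) * Xd)
  meat <- crossprod(Xd * drop(e) / (1 - h))
  V <- XtXi %*% meat %*% XtXi
  list(beta = drop(b), se = sqrt(diag(V)))
}

#' Associate archetype proximity with program scores
#'
#' Per archetype, an ordinary least-squares regression of the patient
#' program score on the patient-to-archetype distance, with HC3
#' heteroskedasticity-consistent standard errors; p-values are adjusted
#' across archetypes (BH by default). An archetype is classed `SLE` when the
#' slope is negative (closer cells in high-score patients) at fdr < `alpha`,
#' `HC` when positive at fdr < `alpha`, else `neutral`. Optionally a
#' permutation p-value is added: plain score permutation without covariates,
#' Freedman-Lane residual permutation with covariates.
#'
#' @param distances patient x k distance matrix (one row per patient).
#' @param program_scores numeric vector aligned to rows.
#' @param covariates optional data.frame of adjustment covariates.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @param alpha fdr threshold for classing (default 0.05).
#' @param n_perm number of permutations (0 = none).
#' @param seed permutation seed.
#' @return data.frame per archetype: `slope`, `se`, `t`, `p`, `fdr`,
#'   `class`, and `p_perm` when requested.
#' @export
associate_archetype_program <- function(distances, program_scores,
                                        covariates = NULL, adjust = "BH",
                                        alpha = 0.05, n_perm = 0L,
                                        seed = 1L) {
  stopifnot(nrow(distances) == length(program_scores))
  k <- ncol(distances)
  Xcov <- if (!is.null(covariates))
    model.matrix(~ ., data = covariates)[, -1L, drop = FALSE] else NULL
  res <- data.frame(archetype = colnames(distances),
                    slope = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  tobs <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    d <- distances[, j]
    if (sd(d) == 0) next
    Xd <- cbind(1, d, Xcov)
    fit <- .hc3_se(Xd, program_scores)
    res$slope[j] <- fit$beta[2L]
    res$se[j] <- fit$se[2L]
    res$t[j] <- fit$beta[2L] / fit$se[2L]
    df <- nrow(Xd) - ncol(Xd)
    res$p[j] <- 2 * pt(-abs(res$t[j]), df)
    tobs[j] <- res$t[j]
  }
  res$fdr <- p.adjust(res$p, method = if (adjust == "BH") "BH" else
    "bonferroni")
  res$class <- ifelse(is.na(res$fdr) | res$fdr >= alpha, "neutral",
                      ifelse(res$slope < 0, "SLE", "HC"))
  if (n_perm > 0L) {
    res$p_perm <- NA_real_
    .with_seed(seed, {
      if (is.null(Xcov)) {
        perm_y <- replicate(n_perm, sample(program_scores))
      } else {
        red <- lm(program_scores ~ Xcov)
        perm_y <- replicate(n_perm, fitted(red) + sample(resid(red)))
      }
      for (j in seq_len(k)) {
        if (is.na(tobs[j])) next
        d <- distances[, j]
        Xd <- cbind(1, d, Xcov)
        tstar <- apply(perm_y, 2L, function(y) {
          f <- .hc3_se(Xd, y)
          f$beta[2L] / f$se[2L]
        })
        res$p_perm[j] <- (1 + sum(abs(tstar) >= abs(tobs[j]))) / (n_perm + 1)
      }
    })
  }
  res
}

#' Cytokine activity of archetype profiles
#'
#' Scores each archetype's expression profile against the cytokine
#' signatures of its own cell type (ULM t-statistics), computes the
#' SLE-versus-HC effect size `delta = mean_SLE - mean_HC` per cytokine with
#' a two-sided Wilcoxon rank-sum test (BH-corrected), and the cosine
#' similarity between SLE-class archetypes restricted to cytokines
#' significant (adjusted p < 0.05) in at least one SLE archetype.
#'
#' @param profiles archetype x gene matrix.
#' @param dictionary named list of weighted sets keyed `"cytokine|celltype"`.
#' @param archetype_celltype character vector, cell type per archetype row.
#' @param archetype_class character vector, `"SLE"`/`"HC"`/`"neutral"` per
#'   archetype row.
#' @return A list of class `cytokine_activity`: `scores`, `padj`
#'   (archetype x cytokine, NA where no own-cell-type set exists), `delta`
#'   (per-cytokine data.frame with Wilcoxon p and fdr), `cosine` (SLE x SLE
#'   similarity, NULL if < 2 SLE archetypes).
#' @export
score_cytokines <- function(profiles, dictionary, archetype_celltype,
                            archetype_class) {
  keysplit <- strsplit(names(dictionary), "|", fixed = TRUE)
  cyt_name <- vapply(keysplit, `[[`, character(1), 1L)
  cyt_ct <- vapply(keysplit, `[[`, character(1), 2L)
  cytokines <- sort(unique(cyt_name))
  n_arch <- nrow(profiles)
  S <- matrix(NA_real_, n_arch, length(cytokines),
              dimnames = list(rownames(profiles), cytokines))
  P <- S
  for (i in seq_len(n_arch)) {
    ct <- archetype_celltype[i]
    own <- which(cyt_ct == ct)
    if (!length(own)) {
      .warnf("no cytokine sets for cell type '%s'; archetype skipped", ct)
      next
    }
    prof <- profiles[i, ]
    for (j in own) {
      out <- tryCatch(score_ulm(prof, dictionary[[j]]),
                      error = function(e) NULL)
      if (!is.null(out)) {
        S[i, cyt_name[j]] <- out$score
        P[i, cyt_name[j]] <- out$p
      }
    }
  }
  padj <- P
  padj[] <- p.adjust(P, method = "BH")

  sle <- which(archetype_class == "SLE")
  hc <- which(archetype_class == "HC")
  delta <- NULL
  if (length(sle) && length(hc)) {
    rows <- list()
    for (cy in cytokines) {
      vs <- S[sle, cy]; vh <- S[hc, cy]
      vs <- vs[!is.na(vs)]; vh <- vh[!is.na(vh)]
      if (!length(vs) || !length(vh)) next
      wt <- suppressWarnings(wilcox.test(vs, vh))
      rows[[cy]] <- data.frame(cytokine = cy,
                               delta = mean(vs) - mean(vh),
                               p = wt$p.value, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      delta <- do.call(rbind, rows)
      delta$fdr <- p.adjust(delta$p, method = "BH")
      delta$significant <- delta$fdr < 0.05
      rownames(delta) <- NULL
    }
  }

  cosine <- NULL
  if (length(sle) >= 2L) {
    sig_cyt <- cytokines[vapply(cytokines, function(cy)
      any(!is.na(padj[sle, cy]) & padj[sle, cy] < 0.05), logical(1))]
    common <- sig_cyt[colSums(is.na(S[sle, sig_cyt, drop = FALSE])) == 0]
    if (length(common) >= 1L) {
      M <- S[sle, common, drop = FALSE]
      nm <- sqrt(rowSums(M^2))
      cosine <- (M %*% t(M)) / (nm %o% nm)
    }
  }
  structure(list(scores = S, padj = padj, delta = delta, cosine = cosine),
            class = "cytokine_activity")
}

#' Link archetype signatures to circulating blood proteins
#'
#' Gene expression is z-scored per gene across the archetypes of each cell
#' type. A protein is retained iff its gene has z > `z_thresh` in at least
#' one SLE-class archetype, in no HC-class archetype, and appears in the
#' supplied elevated-protein list.
#'
#' @param profiles archetype x gene matrix.
#' @param archetype_celltype cell type per archetype row.
#' @param archetype_class `"SLE"`/`"HC"`/`"neutral"` per archetype row.
#' @param protein_list data.frame with `gene` and logical `elevated`.
#' @param z_thresh z-score threshold (default 0.2, strict).
#' @return Character vector of retained protein gene names.
#' @export
link_blood_proteins <- function(profiles, archetype_celltype,
                                archetype_class, protein_list,
                                z_thresh = 0.2) {
  if (!any(archetype_class %in% c("SLE", "HC")))
    .stopf("no SLE/HC class assignments")
  Z <- profiles
  for (ct in unique(archetype_celltype)) {
    rows <- which(archetype_celltype == ct)
    sub <- profiles[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sg <- apply(sub, 2L, sd)
    sg[sg == 0 | is.na(sg)] <- 1
    Z[rows, ] <- sweep(sweep(sub, 2L, mu), 2L, sg, "/")
  }
  elevated <- protein_list$gene[protein_list$elevated]
  cand <- intersect(elevated, colnames(Z))
  sle <- archetype_class == "SLE"
  hc <- archetype_class == "HC"
  keep <- vapply(cand, function(g)
    any(Z[sle, g] > z_thresh) && !any(Z[hc, g] > z_thresh), logical(1))
  cand[keep]
}
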