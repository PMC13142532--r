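# Small shared fixtures and independent oracles, all built in code.

# compact cohort for unit tests (fast: 2 groups x 10 samples, 3 views)
small_cohort <- function(seed = 1L) {
  generate_pseudobulk_cohort(sim_config(
    n_groups = 2L, samples_per_group = 10L, n_celltypes = 3L,
    genes_per_celltype = 120L, seed = seed))
}

fit_small_model <- function(seed = 1L, n_factors = 6L) {
  sim <- small_cohort(seed)
  pb <- qc_filter_samples(sim$cohort)
  views <- lapply(pb$views, function(v)
    normalize_pseudobulk(v[, qc_filter_genes(v), drop = FALSE]))
  groups <- setNames(pb$meta$group, pb$meta$sample_id)
  list(sim = sim, pb = pb, views = views, groups = groups,
       model = fit_factors(views, groups, n_factors = n_factors))
}

# activities with a weak control coupling ct1 -> ct2 that strengthens in
# cases, on otherwise independent cell types
depnet_activities <- function(n, strong, seed) {
  set.seed(seed)
  b <- if (strong) 0.95 else 0.25
  A <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              paste0("ct", 1:5)))
  A[, 2] <- b * A[, 1] +
    sqrt(1 - b^2) * rnorm(n, sd = if (strong) 0.3 else 1)
  scale(A)
}

# brute-force bivariate Moran's I by explicit double loop
moran_brute <- function(x, y, W) {
  if (inherits(W, "spatial_weights")) W <- W$W
  n <- length(x)
  zx <- x - mean(x); zy <- y - mean(y)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + W[i, j] * zx[i] * zy[j]
  (n / sum(W)) * acc / sqrt(sum(zx^2) * sum(zy^2))
}

# brute-force kNN by all-pairs sort with the lowest-index tie rule
knn_brute <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    W[i, order(d, seq_len(n))[seq_len(k)]] <- 1
  }
  W
}

# Breslow partial log-likelihood for a univariate Cox model
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# long-run projected-gradient solver as the simplex-regression oracle
simplex_lsq_oracle <- function(A, p, iters = 20000L) {
  k <- nrow(A)
  s <- rep(1 / k, k)
  G <- A %*% t(A)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  proj <- function(v) {
    u <- sort(v, decreasing = TRUE); css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    pmax(v - (css[rho] - 1) / rho, 0)
  }
  for (it in seq_len(iters)) {
    g <- drop(G %*% s - A %*% p)
    s <- proj(s - g / L)
  }
  s / sum(s)
}
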