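test_that("noiseless vertex data is recovered exactly", {
  verts <- 3 * diag(3)[, 1:2]  # triangle in 2-D
  verts <- rbind(c(0, 0), c(3, 0), c(0, 3))
  X <- verts[rep(1:3, each = 25), ]
  fit <- fit_archetypes(X, 3)
  perm <- mcprogram:::.match_rows(verts, fit$A)
  expect_lt(max(abs(verts - fit$A[perm, ])), 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("RSS descends monotonically on noisy data", {
  set.seed(4)
  X <- matrix(rnorm(300 * 3), 300, 3)
  fit <- fit_archetypes(X, 4, max_iter = 40)
  expect_true(all(diff(fit$rss_path) <= 1e-9))
  expect_error(fit_archetypes(X, 1), ">= 2")
})

test_that("archetypes reconstruct convex data at least as well as k-means", {
  set.seed(5)
  sc <- generate_single_cells(3, 2, 40, 5, 0, noise_sd = 0.05, seed = 5L)
  X <- sc$embedding
  fit <- fit_archetypes(X, 3)
  km <- kmeans(X, centers = 3, nstart = 5)
  expect_lte(fit$rss, sum(km$withinss) * (1 + 1e-8))
})

test_that("the k scan reports an elbow on planted-k data", {
  sc <- generate_single_cells(4, 3, 40, 6, 0, noise_sd = 0.05, seed = 6L)
  scan <- select_k_archetypes(sc$embedding, 2:6, max_iter = 25)
  expect_equal(nrow(scan$table), 5L)
  expect_true(all(diff(scan$table$rss) <= 1e-6))  # rss decreasing in k
  expect_true(scan$best_k %in% 2:6)
})

test_that("bootstrap stability separates structure from noise", {
  verts <- rbind(c(0, 0), c(4, 0), c(0, 4))
  Xv <- verts[rep(1:3, each = 30), ] + matrix(rnorm(180, sd = 0.01), 90)
  fv <- fit_archetypes(Xv, 3)
  sv <- bootstrap_stability(fv, n_boot = 10, seed = 1, max_iter = 20)
  expect_true(all(sv > 0.95))
  set.seed(2)
  Xn <- matrix(rnorm(180), 90, 2)
  fn <- fit_archetypes(Xn, 3, max_iter = 20)
  sn <- bootstrap_stability(fn, n_boot = 10, seed = 1, max_iter = 20)
  expect_true(all(sn >= 0 & sn <= 1))
  expect_lt(mean(sn), mean(sv))
  s1 <- bootstrap_stability(fv, n_boot = 1, seed = 3, max_iter = 10)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("RBF weights follow the closed form with the stored length scale", {
  verts <- rbind(c(0, 0), c(2, 0), c(0, 2))
  X <- rbind(verts[rep(1:3, each = 10), ], c(0.5, 0.5))
  fit <- fit_archetypes(X, 3)
  W <- rbf_weights(fit)
  l <- fit$lengthscale
  expect_equal(l, 0.5 * median(sqrt(rowSums(
    sweep(fit$A, 2, colMeans(X))^2))))
  # a cell sitting on an archetype has weight 1 for it
  perm <- mcprogram:::.match_rows(verts, fit$A)
  expect_equal(unname(W[1, perm[1]]), 1, tolerance = 1e-6)
  # closed form at distance exactly l
  d <- sqrt(rowSums(sweep(X, 2, fit$A[1, ])^2))
  expect_equal(unname(W[, 1]), exp(-d^2 / (2 * l^2)), tolerance = 1e-10)
  # monotone decrease with distance
  ord <- order(d)
  expect_true(all(diff(W[ord, 1]) <= 1e-12))
})

test_that("archetype profiles are weight-normalized means", {
  set.seed(7)
  Z <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  W <- matrix(runif(50 * 3), 50, 3, dimnames = list(NULL, paste0("a", 1:3)))
  P <- archetype_profiles(W, Z)
  # brute-force loop oracle
  for (c in 1:3) for (g in c(1, 10, 20)) {
    acc <- 0
    for (i in 1:50) acc <- acc + W[i, c] * Z[i, g]
    expect_equal(unname(P[c, g]), unname(acc / sum(W[, c])),
                 tolerance = 1e-10)
  }
  # equal weights -> column means; one-hot -> that row
  expect_equal(unname(archetype_profiles(matrix(1, 50, 1), Z)[1, ]),
               unname(colMeans(Z)), tolerance = 1e-12)
  onehot <- matrix(0, 50, 1); onehot[7, 1] <- 1
  expect_equal(unname(archetype_profiles(onehot, Z)[1, ]),
               unname(Z[7, ]), tolerance = 1e-12)
  expect_error(archetype_profiles(matrix(0, 50, 1), Z), "zero total")
})

test_that("hull projection is exact, idempotent, and matches a QP oracle", {
  A <- rbind(a1 = c(0, 0), a2 = c(4, 0), a3 = c(0, 4))
  # interior point: zero deviation and identity projection
  p_in <- matrix(c(1, 1), 1)
  pr <- project_patient_means(p_in, A)
  expect_equal(pr$deviation, 0, tolerance = 1e-8)
  expect_equal(unname(pr$projected), unname(p_in), tolerance = 1e-8)
  # vertex: indicator mixture and zero distance to that archetype
  pr2 <- project_patient_means(matrix(c(4, 0), 1), A)
  expect_equal(unname(pr2$mixtures[1, ]), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(unname(pr2$distances[1, "a2"]), 0)
  # random exterior points vs long-run projected-gradient oracle
  set.seed(8)
  for (i in 1:5) {
    p <- rnorm(2, sd = 4)
    got <- project_patient_means(matrix(p, 1), A)
    want <- simplex_lsq_oracle(A, p)
    expect_equal(unname(got$mixtures[1, ]), unname(want),
                 tolerance = 1e-6)
    # idempotence
    again <- project_patient_means(got$projected, A)
    expect_equal(unname(again$projected), unname(got$projected),
                 tolerance = 1e-8)
    expect_lt(again$deviation, 1e-8)
  }
  # duplicate archetypes remain solvable
  Adup <- rbind(c(0, 0), c(0, 0), c(4, 0))
  prd <- project_patient_means(matrix(c(-1, 0), 1), Adup)
  expect_equal(sum(prd$mixtures), 1, tolerance = 1e-10)
})

test_that("HC3 standard errors match the hat-matrix formula and sandwich", {
  set.seed(9)
  n <- 30
  d <- rnorm(n); y <- 1 - 0.5 * d + rnorm(n, sd = abs(d) + 0.2)
  got <- mcprogram:::.hc3_se(cbind(1, d), y)
  # explicit brute-force hat-matrix computation
  X <- cbind(1, d)
  XtXi <- solve(t(X) %*% X)
  bb <- XtXi %*% t(X) %*% y
  e <- y - X %*% bb
  h <- diag(X %*% XtXi %*% t(X))
  meat <- t(X) %*% diag(as.numeric(e)^2 / (1 - h)^2) %*% X
  se_brute <- sqrt(diag(XtXi %*% meat %*% XtXi))
  expect_equal(got$se, se_brute, tolerance = 1e-8)
  skip_if_not_installed("sandwich")
  fit <- lm(y ~ d)
  se_sand <- sqrt(diag(sandwich::vcovHC(fit, type = "HC3")))
  expect_equal(unname(got$se), unname(se_sand), tolerance = 1e-8)
})

test_that("archetype-program association classifies exact relations", {
  set.seed(10)
  d <- matrix(runif(40 * 3, 0.5, 3), 40, 3,
              dimnames = list(NULL, paste0("a", 1:3)))
  scores <- -d[, 1]  # exactly the negative distance to archetype 1
  res <- associate_archetype_program(d, scores)
  expect_equal(res$slope[1], -1, tolerance = 1e-10)
  expect_equal(res$class[1], "SLE")
  res_p <- associate_archetype_program(d, scores, n_perm = 49, seed = 2)
  expect_lte(res_p$p_perm[1], 1 / 50 + 1e-12)
  # Freedman-Lane path runs with covariates
  covs <- data.frame(age = rnorm(40))
  res_c <- associate_archetype_program(d, scores, covariates = covs,
                                       n_perm = 19, seed = 3)
  expect_true(all(res_c$p_perm >= 1 / 20 - 1e-12))
})

test_that("cytokine scoring restricts to own cell type and finds planted shifts", {
  set.seed(11)
  genes <- paste0("g", 1:60)
  profiles <- matrix(rnorm(4 * 60), 4, 60,
                     dimnames = list(paste0("arch", 1:4), genes))
  planted <- setNames(rnorm(20), genes[1:20])
  # two SLE archetypes aligned with the planted set, two HC anti-aligned
  profiles[1, 1:20] <- 3 * planted + rnorm(20, sd = 0.1)
  profiles[2, 1:20] <- 3 * planted + rnorm(20, sd = 0.1)
  profiles[3, 1:20] <- -3 * planted + rnorm(20, sd = 0.1)
  profiles[4, 1:20] <- -3 * planted + rnorm(20, sd = 0.1)
  dict <- list("IFNlike|T" = planted,
               "other|T" = setNames(rnorm(15), genes[30:44]),
               "foreign|B" = setNames(rnorm(15), genes[40:54]))
  out <- score_cytokines(profiles, dict, rep("T", 4),
                         c("SLE", "SLE", "HC", "HC"))
  # foreign-cell-type cytokine never scored
  expect_true(all(is.na(out$scores[, "foreign"])))
  dlt <- out$delta[out$delta$cytokine == "IFNlike", ]
  expect_gt(dlt$delta, 0)
  # cosine between the two aligned SLE archetypes is ~1 on the diagonal
  if (!is.null(out$cosine)) {
    expect_equal(unname(diag(out$cosine)), rep(1, nrow(out$cosine)),
                 tolerance = 1e-10)
    expect_gt(out$cosine[1, 2], 0.9)
  }
})

test_that("blood-protein linkage applies all three retention clauses", {
  profiles <- rbind(
    archS = c(gA = 5, gB = 5, gC = 5, gD = 0),
    archH = c(gA = 0, gB = 5, gC = 0, gD = 0),
    archN = c(gA = 1, gB = 1, gC = 1, gD = 1))
  classes <- c("SLE", "HC", "neutral")
  plist <- data.frame(gene = c("gA", "gB", "gC"),
                      elevated = c(TRUE, TRUE, FALSE))
  out <- link_blood_proteins(profiles, rep("T", 3), classes, plist)
  expect_true("gA" %in% out)    # up in SLE, not in HC, listed
  expect_false("gB" %in% out)   # also up in the HC archetype
  expect_false("gC" %in% out)   # not flagged elevated
  expect_false("gD" %in% out)   # never upregulated / unlisted
  expect_error(link_blood_proteins(profiles, rep("T", 3),
                                   rep("neutral", 3), plist), "class")
})
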