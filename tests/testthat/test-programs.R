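test_that("ULM equals the closed-form correlation transform", {
  set.seed(1)
  for (i in 1:200) {
    m <- sample(20:200, 1)
    prof <- setNames(rnorm(m), paste0("g", 1:m))
    nset <- sample(3:m, 1)
    gs <- setNames(rnorm(nset), sample(names(prof), nset))
    out <- score_ulm(prof, gs)
    w <- setNames(numeric(m), names(prof)); w[names(gs)] <- gs
    r <- cor(prof, w)
    expect_equal(out$score, r * sqrt(m - 2) / sqrt(1 - r^2),
                 tolerance = 1e-8)
    expect_equal(out$p, 2 * pt(-abs(out$score), m - 2), tolerance = 1e-10)
  }
})

test_that("ULM handles perfect and orthogonal fits", {
  prof <- setNames(rnorm(10), paste0("g", 1:10))
  exact <- score_ulm(prof, prof)  # weights equal the profile
  expect_true(is.finite(exact$score))
  expect_gt(exact$score, 1e6)
  expect_lt(exact$p, 1e-10)
  # constructed r = 0: weights orthogonal to the centered profile
  prof2 <- setNames(c(1, -1, 1, -1, 0, 0), paste0("g", 1:6))
  gs <- setNames(c(1, 1, -1, -1), paste0("g", 1:4))  # exact orthogonality
  out <- score_ulm(prof2, gs)
  expect_equal(out$score, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
  expect_error(score_ulm(prof, setNames(1:3, c("x", "y", "z"))), "fewer")
})

test_that("activity matrices duplicate rows faithfully and z-standardize", {
  set.seed(3)
  mat <- matrix(rnorm(5 * 50), 5, 50,
                dimnames = list(paste0("s", 1:5), paste0("g", 1:50)))
  sets <- list(a = setNames(rnorm(10), paste0("g", 1:10)),
               b = setNames(rnorm(8), paste0("g", 20:27)))
  act <- score_activities(mat, sets)
  dup <- score_activities(mat[c(1:5, 1), ], sets)
  expect_equal(unname(dup$scores[6, ]), unname(dup$scores[1, ]))
  z <- score_activities(mat, sets, zscore = TRUE)
  expect_equal(unname(colMeans(z$scores)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z$scores, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_warning(
    score_activities(mat, c(sets, list(tiny = setNames(1, "g1")))),
    "dropping")
})

test_that("activity of the planted loading set tracks the true score", {
  fx <- fit_small_model(6L)
  w <- fx$sim$truth$true_loadings[[1]][, 1]
  act <- score_activities(fx$views[[1]],
                          list(planted = w[w != 0]))
  truth <- fx$sim$truth$true_scores[rownames(fx$views[[1]]), 1]
  expect_gt(abs(cor(act$scores[, 1], truth)), 0.8)
})

test_that("coordinated signatures follow the retention and averaging rules", {
  # two selected cell types via a synthetic model skeleton
  model <- structure(list(
    w = list(ct1 = cbind(F1 = c(g1 = 0.6, g2 = 0.49, g3 = -1.0)),
             ct2 = cbind(F1 = c(g1 = 0.2, g2 = 0.49, g3 = 0.8))),
    r2 = data.frame(group = "g1", celltype = c("ct1", "ct2"),
                    factor = "F1", r2 = c(0.3, 0.25)),
    z_all = matrix(0, 1, 1, dimnames = list("s1", "F1"))),
    class = "factor_model")
  net <- list(cv_r2 = c(ct1 = 0.9, ct2 = 0.9))
  sig <- coordinated_signature(model, net, "F1", w_thresh = 0.5)
  # g1: retained only in ct1 (0.6 vs 0.2) -> weight 0.6
  expect_equal(unname(sig["g1"]), 0.6)
  # g2: |w| = 0.49 everywhere -> excluded
  expect_false("g2" %in% names(sig))
  # g3: retained in both -> mean(-1.0, 0.8)
  expect_equal(unname(sig["g3"]), mean(c(-1.0, 0.8)))

  # restricted factor: only the single high-variance cell type used
  model$r2$r2 <- c(0.3, 0.05)
  sig2 <- coordinated_signature(model, NULL, "F1", w_thresh = 0.5)
  expect_setequal(names(sig2), c("g1", "g3"))
  expect_equal(unname(sig2["g3"]), -1.0)
})

test_that("bulk mapping is a convex, scale-invariant cell-type average", {
  fx <- fit_small_model(7L)
  m <- fx$model
  set.seed(8)
  bulk <- matrix(rnorm(6 * 200), 6,
                 dimnames = list(paste0("b", 1:6),
                                 unique(unlist(lapply(fx$views, colnames)))[1:200]))
  mp <- map_programs_bulk(bulk, m, factors = "Factor1")
  cols <- grep("Factor1", colnames(mp$per_celltype), value = TRUE)
  pc <- mp$per_celltype[, cols, drop = FALSE]
  wts <- mp$weights$Factor1[sub("^Factor1\\|", "", cols)]
  wts <- wts / sum(wts)
  expect_equal(unname(mp$wmean[, "Factor1"]),
               unname(drop(pc %*% wts)), tolerance = 1e-10)
  # convexity: the weighted mean lies within the per-cell-type range
  expect_true(all(mp$wmean[, 1] >= apply(pc, 1, min) - 1e-10))
  expect_true(all(mp$wmean[, 1] <= apply(pc, 1, max) + 1e-10))
})

test_that("planted bulk signal is recovered by program mapping", {
  fx <- fit_small_model(9L)
  m <- fx$model
  truth <- fx$sim$truth
  set.seed(10)
  score <- truth$true_scores[, 1]
  w1 <- truth$true_loadings[[1]][, 1]
  genes <- unique(unlist(lapply(fx$views, colnames)))
  bulk <- matrix(rnorm(length(score) * length(genes), sd = 0.5),
                 length(score), length(genes),
                 dimnames = list(names(score), genes))
  bulk[, names(w1)] <- bulk[, names(w1)] + outer(score, w1)
  mp <- map_programs_bulk(bulk, m)
  f_mc <- colnames(m$z_all)[which.max(abs(cor(score, m$z_all)))]
  expect_gt(abs(cor(mp$wmean[, f_mc], score)), 0.8)
})

test_that("CCC scores gate on detection and take geometric means", {
  me <- list(A = rbind(s1 = c(L1 = 4, R1 = 1), s2 = c(L1 = 4, R1 = 1)),
             B = rbind(s1 = c(L1 = 0, R1 = 9), s2 = c(L1 = 2, R1 = 0)))
  df <- list(A = rbind(s1 = c(L1 = 0.5, R1 = 0.5),
                       s2 = c(L1 = 0.09, R1 = 0.5)),
             B = rbind(s1 = c(L1 = 0.2, R1 = 0.5),
                       s2 = c(L1 = 0.2, R1 = 0.9)))
  lr <- data.frame(ligand = "L1", receptor = "R1")
  tab <- score_ccc(me, df, lr)
  key <- paste("A", "L1", "R1", "B", sep = "^")
  expect_equal(unname(tab$scores[key, "s1"]), 6)       # sqrt(4 * 9)
  expect_equal(unname(tab$scores[key, "s2"]), 0)       # 9% detection
  key2 <- paste("B", "L1", "R1", "B", sep = "^")
  expect_equal(unname(tab$scores[key2, "s2"]), 0)      # zero receptor
})

test_that("CCC view filters are faithful and monotone", {
  set.seed(5)
  n_s <- 10L
  rows <- data.frame(source = rep(c("A", "B"), each = 5),
                     ligand = paste0("L", 1:10),
                     receptor = paste0("R", 1:10),
                     target = "C", stringsAsFactors = FALSE)
  sc <- matrix(runif(10 * n_s), 10, n_s,
               dimnames = list(paste(rows$source, rows$ligand,
                                     rows$receptor, rows$target, sep = "^"),
                               paste0("s", 1:n_s)))
  sc[1, ] <- c(rep(0, 8), 1, 1)   # nonzero in 20% < 30% -> dropped
  tab <- structure(list(rows = rows, scores = sc), class = "lr_table")
  keep_all <- filter_ccc_views(tab, lr_prop = 0, min_inter = 0L,
                               min_lr = 0L, min_samples = 0L)
  expect_equal(nrow(keep_all$rows), 10L)
  f1 <- filter_ccc_views(tab, lr_prop = 0.3, min_inter = 0L, min_lr = 0L,
                         min_samples = 0L)
  expect_false(rownames(sc)[1] %in% rownames(f1$scores))
  # network restriction drops views regardless of scores
  f2 <- filter_ccc_views(tab, lr_prop = 0, min_inter = 0L, min_lr = 0L,
                         min_samples = 0L,
                         net_edges = data.frame(source = "A", target = "C"))
  expect_true(all(f2$rows$source == "A"))
  # monotonicity: tightening any threshold never adds rows
  for (args in list(list(lr_prop = 0.5), list(min_lr = 6L),
                    list(min_samples = 11L), list(min_inter = 11L))) {
    f3 <- do.call(filter_ccc_views, c(list(tab = tab),
      utils::modifyList(list(lr_prop = 0.3, min_inter = 0L, min_lr = 0L,
                             min_samples = 0L), args)))
    expect_lte(nrow(f3$rows), nrow(f1$rows))
  }
})

test_that("program correlation keeps strong positive interactions only", {
  set.seed(6)
  ps <- setNames(rnorm(40), paste0("s", 1:40))
  rows <- data.frame(source = c("A", "A", "B"), ligand = paste0("L", 1:3),
                     receptor = paste0("R", 1:3), target = "C",
                     stringsAsFactors = FALSE)
  sc <- rbind(ps,                        # r = 1, kept
              -ps,                       # r = -1, dropped
              rnorm(40) * 0.01 + 0.29 * ps / sd(ps))  # weak
  rownames(sc) <- paste(rows$source, rows$ligand, rows$receptor,
                        rows$target, sep = "^")
  colnames(sc) <- names(ps)
  tab <- structure(list(rows = rows, scores = sc), class = "lr_table")
  out <- correlate_ccc_program(tab, ps)
  expect_true(out$table$keep[1])
  expect_false(out$table$keep[2])
  expect_equal(out$summary$n_as_sender[out$summary$celltype == "A"],
               sum(out$table$keep[out$table$source == "A"]))
  # constant row is dropped, not kept
  sc2 <- sc; sc2[1, ] <- 5
  tab2 <- structure(list(rows = rows, scores = sc2), class = "lr_table")
  out2 <- correlate_ccc_program(tab2, ps)
  expect_equal(nrow(out2$table), 2L)
})
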