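test_that("control z-scoring centres controls and drops unusable genes", {
  set.seed(1)
  mu <- setNames(c(10, 5, 3), c("g1", "g2", "g3"))
  sg <- setNames(c(2, 1, 0), names(mu))
  bulk <- rbind(s1 = c(g1 = 10, g2 = 7, g3 = 5),
                s2 = c(g1 = 14, g2 = 5, g3 = 1))
  z <- suppressWarnings(zscore_to_controls(bulk, mu, sg))
  expect_equal(unname(z["s1", "g1"]), 0)
  expect_equal(unname(z["s2", "g1"]), 2)  # mu + 2 sigma
  expect_false("g3" %in% colnames(z))     # zero control SD
  # applied to the controls themselves: mean ~ 0, sd ~ 1 per gene
  ctrl <- matrix(rnorm(200, 5, 2), 100, 2,
                 dimnames = list(NULL, c("g1", "g2")))
  zc <- zscore_to_controls(ctrl, colMeans(ctrl), apply(ctrl, 2, sd))
  expect_equal(unname(colMeans(zc)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(zc, 2, sd)), c(1, 1), tolerance = 1e-10)
})

test_that("remission labelling follows the flare window rules", {
  mkv <- function(days, sled) data.frame(patient = "p1", day = days,
                                         sledai = sled)
  # flare of +5 at day 60 inside the 91-day window
  v1 <- label_remission_visits(mkv(c(0, 60, 200), c(1, 6, 1)))
  expect_equal(v1$label[1], "short_term")
  expect_equal(v1$event[1], "flare")
  expect_equal(v1$time_to_next[1], 60)
  # delta 2 < 4: not short term; long-term when last SLEDAI < 2 and
  # follow-up > 90 days
  v2 <- label_remission_visits(mkv(c(0, 60, 200), c(1, 3, 1)))
  expect_equal(v2$label[1], "long_term")
  # SLEDAI 3 at index is not remission
  v3 <- label_remission_visits(mkv(c(0, 60, 200), c(3, 1, 1)))
  expect_false(v3$remission[1])
  expect_true(is.na(v3$label[1]))
  # long-term denied when the last recorded SLEDAI is 2 (not < 2)
  v4 <- label_remission_visits(mkv(c(0, 60, 200), c(1, 3, 2)))
  expect_equal(v4$label[1], "excluded")
  # flare beyond the window is not short-term
  v5 <- label_remission_visits(mkv(c(0, 120, 200), c(1, 6, 1)))
  expect_false(identical(v5$label[1], "short_term"))
  # single-visit patients are excluded
  v6 <- label_remission_visits(data.frame(patient = "p1", day = 0,
                                          sledai = 1))
  expect_equal(v6$label[1], "excluded")
})

test_that("every remission visit receives exactly one label", {
  vt <- generate_longitudinal(40, 5, beta_flare = 1, seed = 3L)
  lab <- label_remission_visits(vt)
  rem <- lab[lab$remission, ]
  expect_true(all(rem$label %in% c("short_term", "long_term", "excluded")))
  expect_true(all(is.na(lab$label[!lab$remission])))
})

test_that("pre-flare testing uses Welch t with Holm correction", {
  set.seed(4)
  acts <- cbind(flat = rnorm(40), up = c(rnorm(20, 2), rnorm(20, 0)))
  labels <- rep(c("short_term", "long_term"), each = 20)
  out <- test_preflare(acts, labels)
  expect_equal(out$t[1], t.test(acts[1:20, 1], acts[21:40, 1])$statistic,
               ignore_attr = TRUE)
  expect_gt(out$t[2], 4)  # elevated before flare
  expect_equal(out$p_holm, p.adjust(out$p, "holm"))
  # identical group means give t ~ 0
  same <- cbind(x = rep(c(1, 2), 20))
  expect_equal(test_preflare(same, labels)$t, 0, tolerance = 1e-12)
  # Holm oracle on (0.01, 0.04): (0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_error(test_preflare(acts, rep("long_term", 40)), ">= 2")
})

test_that("the Cox partial likelihood matches brute-force optimization", {
  # 4-observation instance with a finite partial-likelihood optimum
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 0); x <- c(1, 0, 0, 1)
  fit <- fit_cox(data.frame(x = x), time, event)
  brute <- optimize(function(b) -cox_partial_loglik(b, time, event, x),
                    c(-10, 10), tol = 1e-10)
  expect_equal(fit$coefficients$beta, brute$minimum, tolerance = 1e-6)
  expect_equal(fit$loglik, -brute$objective, tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))
  expect_true(fit$coefficients$lower95 <= fit$coefficients$hr &
                fit$coefficients$hr <= fit$coefficients$upper95)
})

test_that("Cox recovery and null calibration behave on generated visits", {
  vt <- generate_longitudinal(300, 4, beta_flare = 1, seed = 5L)
  v <- vt[!is.na(vt$time_to_next), ]
  fit <- fit_cox(data.frame(activity = v$activity), v$time_to_next,
                 v$event == "flare")
  expect_lt(abs(fit$coefficients$beta - 1), 0.3)
  # null: the estimate is centred on zero across seeds, C-index ~ 0.5
  null_fits <- lapply(1:25, function(s) {
    vt0 <- generate_longitudinal(60, 4, beta_flare = 0, seed = 100L + s)
    v0 <- vt0[!is.na(vt0$time_to_next), ]
    fit_cox(data.frame(activity = v0$activity), v0$time_to_next,
            v0$event == "flare")
  })
  betas <- vapply(null_fits, function(f) f$coefficients$beta, numeric(1))
  ses <- vapply(null_fits, function(f) f$coefficients$se, numeric(1))
  expect_lt(abs(mean(betas)), 2 * mean(ses) / sqrt(length(betas)))
  vt0 <- generate_longitudinal(500, 3, beta_flare = 0, seed = 6L)
  v0 <- vt0[!is.na(vt0$time_to_next), ]
  fit0 <- fit_cox(data.frame(activity = v0$activity), v0$time_to_next,
                  v0$event == "flare")
  expect_lt(abs(fit0$c_index - 0.5), 0.05)
  # LRT against a nested base model
  f2 <- fit_cox(data.frame(activity = v$activity, junk = rnorm(nrow(v))),
                v$time_to_next, v$event == "flare",
                nested_base = "activity")
  expect_true(f2$lrt_p > 0.001)
  expect_equal(f2$lrt_df, 1L)
  expect_error(fit_cox(data.frame(x = 1:3), c(0, 1, 2), c(1, 1, 0)),
               "zero or negative")
})

test_that("the gene screen restricts membership and finds planted risk genes", {
  vt <- generate_longitudinal(150, 4, beta_flare = 1.2, seed = 7L)
  v <- vt[!is.na(vt$time_to_next), ]
  z <- attr(vt, "expression")[rownames(v), ]
  tr <- attr(vt, "truth")
  sigs <- list("IFN|ct1" = tr$signature_weights,
               "IFN|ct2" = tr$signature_weights[1:5],
               "NFkB|ct1" = setNames(rnorm(4), paste0("bg", 1:4)))
  plist <- data.frame(gene = c(names(tr$signature_weights)[1:6], "bg1"),
                      elevated = c(rep(TRUE, 6), FALSE))
  out <- gene_flare_screen(z, sigs, plist, v$time_to_next,
                           v$event == "flare")
  # bg1 not elevated -> excluded despite signature membership
  expect_false("bg1" %in% out$fits$gene)
  # membership counts per program
  expect_equal(unname(out$membership["sg1", "IFN"]), 2L)
  expect_equal(unname(out$membership["sg6", "IFN"]), 1L)
  # planted risk genes trend hazardous
  expect_gt(mean(out$fits$hr > 1), 0.5)
  empty <- gene_flare_screen(z, sigs,
                             data.frame(gene = "none", elevated = TRUE),
                             v$time_to_next, v$event == "flare")
  expect_equal(nrow(empty$fits), 0L)
})
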