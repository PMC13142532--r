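#' Z-score bulk expression against healthy-control statistics
#'
#' `z = (x - mu_ctrl) / sigma_ctrl` per gene. Genes with missing values or
#' zero control SD are removed (the latter with a warning).
#'
#' @param bulk sample x gene matrix.
#' @param ctrl_mean,ctrl_sd named per-gene control statistics.
#' @return sample x gene z-score matrix over the usable genes.
#' @export
zscore_to_controls <- function(bulk, ctrl_mean, ctrl_sd) {
  genes <- intersect(colnames(bulk), names(ctrl_mean))
  genes <- intersect(genes, names(ctrl_sd))
  ok_missing <- genes[colSums(is.na(bulk[, genes, drop = FALSE])) == 0 &
                        !is.na(ctrl_mean[genes]) & !is.na(ctrl_sd[genes])]
  zero_sd <- ok_missing[ctrl_sd[ok_missing] == 0]
  if (length(zero_sd))
    .warnf("dropping %d gene(s) with zero control SD", length(zero_sd))
  genes <- setdiff(ok_missing, zero_sd)
  sweep(sweep(bulk[, genes, drop = FALSE], 2L, ctrl_mean[genes]), 2L,
        ctrl_sd[genes], "/")
}

#' Label remission visits by subsequent flare
#'
#' A remission visit (SLEDAI < 3) is labelled `short_term` when a flare
#' (SLEDAI increase of at least `flare_delta` relative to the index visit)
#' occurs at the next follow-up within `window_days`; `long_term` when no
#' flare occurs within the window, the patient's last recorded SLEDAI is
#' below `longterm_sledai`, and the patient's cumulative follow-up exceeds
#' `min_followup` days; otherwise `excluded`. Survival time is days from the
#' index to the next visit, with flare at that visit as the event.
#' Non-remission visits carry no label; single-visit patients are excluded.
#'
#' @param visits data.frame with `patient`, `day`, `sledai` (chronological
#'   within patient, or sortable by `day`).
#' @param window_days flare window, 91 (3 months) or 182 (6 months).
#' @param remission_max maximum SLEDAI counting as remission (default 2.99,
#'   i.e. SLEDAI < 3).
#' @param flare_delta SLEDAI increase defining a flare (default 4).
#' @param longterm_sledai strict upper bound on the last recorded SLEDAI for
#'   long-term remission (default 2).
#' @param min_followup minimum cumulative follow-up in days (strict,
#'   default 90).
#' @return The input with added columns `remission`, `label`
#'   (`short_term`/`long_term`/`excluded`, NA off remission),
#'   `time_to_next`, `event` (`"flare"`/`"none"`).
#' @export
label_remission_visits <- function(visits, window_days = 91,
                                   remission_max = 2.99, flare_delta = 4,
                                   longterm_sledai = 2, min_followup = 90) {
  v <- visits[order(visits$patient, visits$day), , drop = FALSE]
  v$remission <- v$sledai <= remission_max
  v$label <- NA_character_
  v$time_to_next <- NA_real_
  v$event <- NA_character_
  for (p in unique(v$patient)) {
    idx <- which(v$patient == p)
    followup <- v$day[idx[length(idx)]] - v$day[idx[1L]]
    last_sledai <- v$sledai[idx[length(idx)]]
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!v$remission[i]) next
      if (ii == length(idx)) { v$label[i] <- "excluded"; next }
      j <- idx[ii + 1L]
      dt <- v$day[j] - v$day[i]
      flare <- (v$sledai[j] - v$sledai[i]) >= flare_delta
      v$time_to_next[i] <- dt
      v$event[i] <- if (flare) "flare" else "none"
      v$label[i] <- if (flare && dt <= window_days) "short_term"
        else if (!(flare && dt <= window_days) &&
                 last_sledai < longterm_sledai &&
                 followup > min_followup) "long_term"
        else "excluded"
    }
  }
  v
}

#' Pre-flare activity differences between remission strata
#'
#' Welch two-sample t-test per activity column between `short_term` and
#' `long_term` visits; positive t means higher activity before a flare.
#' P-values are Holm-adjusted across columns, with significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param activities visit x (program or program-celltype) matrix, typically
#'   including a weighted-mean aggregate column.
#' @param labels character vector per visit row (`short_term` /
#'   `long_term` / other).
#' @return data.frame per column: `t`, `p`, `p_holm`, `stars`.
#' @export
test_preflare <- function(activities, labels) {
  st <- labels == "short_term" & !is.na(labels)
  lt <- labels == "long_term" & !is.na(labels)
  if (sum(st) < 2L || sum(lt) < 2L)
    .stopf("need >= 2 visits in each remission stratum")
  out <- data.frame(feature = colnames(activities), t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(activities))) {
    tt <- t.test(activities[st, j], activities[lt, j])
    out$t[j] <- unname(tt$statistic)
    out$p[j] <- tt$p.value
  }
  out$p_holm <- p.adjust(out$p, method = "holm")
  out$stars <- cut(out$p_holm, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out
}

#' Cox proportional-hazards fit with Breslow ties
#'
#' Fits a Cox model by partial likelihood (Breslow tie handling), reporting
#' hazard ratios with Wald 95% confidence intervals, Harrell's concordance
#' index, and, when a nested base model is supplied, a likelihood-ratio test
#' for the added covariates.
#'
#' @param covariates data.frame or matrix of covariates (columns named).
#' @param time survival times (> 0).
#' @param event 0/1 or logical event indicator (>= 1 event required).
#' @param nested_base optional character vector naming the covariates of the
#'   nested base model for the LRT.
#' @return A list of class `cox_fit`: `coefficients` (beta, HR, CI, p per
#'   covariate), `loglik`, `c_index`, and `lrt_p`/`lrt_df` when requested.
#' @export
fit_cox <- function(covariates, time, event, nested_base = NULL) {
  X <- as.data.frame(covariates)
  if (any(time <= 0)) .stopf("zero or negative survival times")
  ev <- as.integer(event %in% c(1, TRUE) | event == "flare")
  if (sum(ev) < 1L) .stopf("need at least one event")
  dat <- cbind(data.frame(.time = time, .event = ev), X)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(X), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (any(is.na(coef(fit)))) .stopf("Cox fit failed to converge")
  sm <- summary(fit)
  co <- data.frame(covariate = rownames(sm$coefficients),
                   beta = sm$coefficients[, "coef"],
                   hr = sm$coefficients[, "exp(coef)"],
                   lower95 = sm$conf.int[, "lower .95"],
                   upper95 = sm$conf.int[, "upper .95"],
                   se = sm$coefficients[, "se(coef)"],
                   p = sm$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE)
  rownames(co) <- NULL
  out <- list(coefficients = co, loglik = fit$loglik[2L],
              c_index = unname(sm$concordance["C"]), model = fit)
  if (!is.null(nested_base)) {
    if (!all(nested_base %in% names(X)))
      .stopf("nested_base covariates must be a subset of the model")
    fml0 <- if (length(nested_base))
      stats::as.formula(paste("survival::Surv(.time, .event) ~",
                              paste(nested_base, collapse = " + ")))
    else stats::as.formula("survival::Surv(.time, .event) ~ 1")
    fit0 <- survival::coxph(fml0, data = dat, ties = "breslow")
    ll0 <- if (length(nested_base)) fit0$loglik[2L] else fit0$loglik[1L]
    df <- length(coef(fit)) - length(nested_base)
    lrt <- 2 * (fit$loglik[2L] - ll0)
    out$lrt_p <- pchisq(lrt, df = df, lower.tail = FALSE)
    out$lrt_df <- df
  }
  structure(out, class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("loglik = %.3f, C-index = %.3f\n", x$loglik, x$c_index))
  invisible(x)
}

#' Per-gene flare-risk screen over program signature genes
#'
#' Restricts to genes that are members of at least one supplied signature
#' and appear in the elevated blood-protein list, fits a univariate Cox
#' model per gene, and counts per program the number of cell-type
#' signatures containing the gene.
#'
#' @param z visit x gene z-score matrix.
#' @param signatures named list of weighted gene sets; names formatted
#'   `"program|celltype"`.
#' @param protein_list data.frame with `gene` and logical `elevated`.
#' @param time,event survival outcome per visit row.
#' @return A list: `fits` (per gene beta/HR/CI/p) and `membership` (gene x
#'   program counts). Empty gene set gives empty results.
#' @export
gene_flare_screen <- function(z, signatures, protein_list, time, event) {
  sig_genes <- unique(unlist(lapply(signatures, names)))
  elevated <- protein_list$gene[protein_list$elevated]
  genes <- intersect(intersect(sig_genes, elevated), colnames(z))
  programs <- unique(vapply(strsplit(names(signatures), "|", fixed = TRUE),
                            `[[`, character(1), 1L))
  if (!length(genes))
    return(list(fits = data.frame(), membership = matrix(
      0L, 0L, length(programs), dimnames = list(NULL, programs))))
  fits <- do.call(rbind, lapply(genes, function(g) {
    f <- fit_cox(data.frame(x = z[, g]), time, event)
    data.frame(gene = g, beta = f$coefficients$beta,
               hr = f$coefficients$hr,
               lower95 = f$coefficients$lower95,
               upper95 = f$coefficients$upper95,
               p = f$coefficients$p, stringsAsFactors = FALSE)
  }))
  membership <- matrix(0L, length(genes), length(programs),
                       dimnames = list(genes, programs))
  for (nm in names(signatures)) {
    pr <- strsplit(nm, "|", fixed = TRUE)[[1L]][1L]
    hit <- intersect(genes, names(signatures[[nm]]))
    membership[hit, pr] <- membership[hit, pr] + 1L
  }
  list(fits = fits, membership = membership)
}
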