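#' Per-cell-type program activity scores
#'
#' Scores every sample's normalized pseudobulk profile in each cell type
#' against that cell type's gene loadings for one factor (ULM t-statistics),
#' then z-standardizes each cell-type column across samples — the input
#' convention of the dependency-network stage.
#'
#' @param model fitted `factor_model`.
#' @param views named list of normalized sample x gene views.
#' @param factor factor id.
#' @param zscore standardize columns (default TRUE).
#' @return sample x celltype activity matrix (NA where a sample is absent
#'   from a view).
#' @export
program_activities <- function(model, views, factor, zscore = TRUE) {
  samples <- sort(unique(unlist(lapply(views, rownames))))
  A <- matrix(NA_real_, length(samples), length(views),
              dimnames = list(samples, names(views)))
  for (ct in names(views)) {
    w <- model$w[[ct]][, factor]
    act <- score_activities(views[[ct]], setNames(list(w), ct))
    A[rownames(views[[ct]]), ct] <- act$scores[, 1L]
  }
  if (zscore) {
    mu <- colMeans(A, na.rm = TRUE)
    sg <- apply(A, 2L, sd, na.rm = TRUE)
    sg[sg == 0 | is.na(sg)] <- 1
    A <- sweep(sweep(A, 2L, mu), 2L, sg, "/")
  }
  A
}

#' Run the full patient-map pipeline on synthetic data
#'
#' Exercises every stage end-to-end with planted ground truth: cohort
#' simulation, pseudobulk QC and normalization, multi-group factorization,
#' program selection and covariate association, per-cell-type activities and
#' dependency networks, the coordinated gene signature, ligand-receptor
#' scoring restricted to network edges, archetypal analysis with program
#' association and cytokine/protein linkage, longitudinal flare labelling
#' and Cox modelling, and spatial co-localization with glomerular
#' enrichment. Intended for validation and as a worked example; every stage
#' returns its full result object.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param cfg optional [sim_config()] (its seed is overridden by `seed`).
#' @return Named list of stage outputs, including `recovery` (correlations
#'   of fitted vs planted group-centred scores) and `truth`.
#' @export
run_patient_map_pipeline <- function(seed = 1L, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed) else cfg$seed <- seed

  ## 1. simulate + pseudobulk QC
  sim <- generate_pseudobulk_cohort(cfg)
  pb <- qc_filter_samples(sim$cohort)
  views <- lapply(pb$views, function(v)
    normalize_pseudobulk(v[, qc_filter_genes(v), drop = FALSE]))
  groups <- setNames(pb$meta$group, pb$meta$sample_id)

  ## 2. factor model
  model <- fit_factors(views, groups, n_factors = 10)
  programs <- select_programs(model$r2)
  zt <- sim$truth$true_scores
  grp <- groups[rownames(zt)]
  ztc <- zt - apply(zt, 2L, function(col) stats::ave(col, grp))
  cors <- abs(cor(ztc, model$z_all))
  f_mc <- colnames(cors)[which.max(cors[1L, ])]
  f_rs <- colnames(cors)[which.max(cors[2L, ])]
  recovery <- list(r_multicellular = max(cors[1L, ]),
                   r_restricted = max(cors[2L, ]),
                   factor_multicellular = f_mc, factor_restricted = f_rs)

  ## 3. covariate association
  meta <- pb$meta[match(rownames(model$z_all), pb$meta$sample_id), ]
  assoc <- associate_covariates(model$z_all,
                                meta[, c("condition", "sledai", "age",
                                         "sex")])

  ## 4. activities + dependency networks
  act <- program_activities(model, views, f_mc)
  act <- act[stats::complete.cases(act), , drop = FALSE]
  cond <- meta$condition[match(rownames(act), meta$sample_id)]
  net_all <- fit_dependency_network(act, fold_seed = seed)
  net_hc <- fit_dependency_network(act, mask = cond == "control",
                                   condition = "control", fold_seed = seed)
  net_sle <- fit_dependency_network(act, mask = cond == "case",
                                    condition = "case", fold_seed = seed)
  edges <- classify_edges(net_hc, net_sle)

  ## 5. coordinated signature of the multicellular program
  signature <- coordinated_signature(model, net_all, f_mc, rescale = TRUE)

  ## 6. priors + ligand-receptor stage (expression-magnitude scores gated
  ## on detection, filtered to network edges)
  universe <- unique(unlist(lapply(views, colnames)))
  priors <- generate_priors(universe, names(views),
                            planted_set = signature, seed = seed + 1L)
  mean_expr <- lapply(names(pb$views), function(ct) {
    v <- pb$views[[ct]]
    v / pmax(pb$cell_counts[ct, rownames(v)], 1)
  })
  names(mean_expr) <- names(pb$views)
  detect_frac <- lapply(mean_expr, function(m) pmin(m / (m + 0.5), 1))
  ccc <- score_ccc(mean_expr, detect_frac, priors$lr)
  ccc_f <- filter_ccc_views(ccc, min_inter = 5L, min_lr = 5L,
                            min_samples = 30L,
                            net_edges = network_edges(net_all))
  prog_scores <- setNames(model$z_all[, f_mc], rownames(model$z_all))
  ccc_sel <- if (nrow(ccc_f$rows) > 0)
    correlate_ccc_program(ccc_f, prog_scores) else NULL

  ## 7. archetypes on single cells coupled to the program score
  cells <- generate_single_cells(k = 3L, dim = 2L, cells_per_patient = 15L,
                                 n_patients = 40L, coupling = 1,
                                 seed = seed + 2L)
  arch <- fit_archetypes(cells$embedding, 3L, max_iter = 30L)
  pmeans <- t(vapply(split(seq_len(nrow(cells$embedding)), cells$patient),
                     function(i) colMeans(cells$embedding[i, , drop = FALSE]),
                     numeric(ncol(cells$embedding))))
  pmeans <- pmeans[names(cells$patient_scores), , drop = FALSE]
  proj <- project_patient_means(pmeans, arch$A)
  arch_assoc <- associate_archetype_program(proj$distances,
                                            cells$patient_scores)
  zexpr <- scale(cells$expression)
  profiles <- archetype_profiles(rbf_weights(arch), zexpr)
  cyto <- NULL
  proteins <- character()
  ng <- ncol(profiles)
  if (any(arch_assoc$class == "SLE")) {
    dict <- list()
    for (a in seq_len(3L)) dict[[paste0("CKa", a, "|cells")]] <-
      setNames(profiles[a, seq_len(ng)], colnames(profiles)[seq_len(ng)])
    cyto <- score_cytokines(profiles, dict, rep("cells", 3L),
                            arch_assoc$class)
    plist <- data.frame(gene = colnames(profiles)[seq_len(ng)],
                        elevated = TRUE, stringsAsFactors = FALSE)
    if (any(arch_assoc$class == "HC"))
      proteins <- link_blood_proteins(profiles, rep("cells", 3L),
                                      arch_assoc$class, plist)
  }

  ## 8. longitudinal flare modelling
  visits <- generate_longitudinal(n_patients = 120L, visits_per_patient = 4L,
                                  beta_flare = 1, seed = seed + 3L)
  vexpr <- attr(visits, "expression")
  sig_lt <- attr(visits, "truth")$signature_weights
  vact <- score_activities(vexpr, list(program = sig_lt))$scores[, 1L]
  labelled <- label_remission_visits(visits)
  lab <- labelled$label
  pre <- if (sum(lab == "short_term", na.rm = TRUE) >= 2 &&
             sum(lab == "long_term", na.rm = TRUE) >= 2)
    test_preflare(cbind(wmean = vact[rownames(labelled)]), lab) else NULL
  risk <- labelled[!is.na(labelled$time_to_next), ]
  cox <- fit_cox(data.frame(activity = vact[rownames(risk)]),
                 risk$time_to_next, risk$event == "flare")

  ## 9. spatial co-localization + glomerular context
  slides <- generate_spatial(seed = seed + 4L)
  per_slide <- do.call(rbind, lapply(seq_along(slides), function(i) {
    sl <- slides[[i]]
    W <- knn_weights(sl$coords, 6L)
    mp <- moran_permutation_p(sl$features$program,
                              sl$features$abundance[, "IMM"], W,
                              seed = seed + 10L + i)
    data.frame(celltype = "IMM", program = "program",
               condition = sl$condition, slide = i, I = mp$I, p = mp$p,
               stringsAsFactors = FALSE)
  }))
  coloc <- aggregate_colocalization(per_slide)
  sl1 <- slides[[1L]]
  sv <- build_views(sl1$compositions, sl1$coords,
                    sl1$annotations$glomerular)
  multiview <- fit_multiview(sv, "IMM", seed = seed)
  glom_scores <- cbind(program = sl1$features$program)
  rownames(glom_scores) <- rownames(sl1$coords)
  all_spots <- do.call(rbind, lapply(slides, function(sl)
    data.frame(score = sl$features$program,
               glom = sl$annotations$glomerular,
               immune = sl$compositions[, "IMM"],
               condition = sl$condition, stringsAsFactors = FALSE)))
  glom <- glomerular_enrichment(cbind(program = all_spots$score),
                                all_spots$glom, all_spots$immune,
                                all_spots$condition)

  list(config = cfg, cohort = pb, model = model, programs = programs,
       recovery = recovery, covariates = assoc, activities = act,
       networks = list(all = net_all, hc = net_hc, sle = net_sle),
       edges = edges, signature = signature, ccc = ccc_sel,
       archetypes = list(model = arch, association = arch_assoc,
                         cytokines = cyto, proteins = proteins),
       longitudinal = list(visits = labelled, preflare = pre, cox = cox),
       spatial = list(per_slide = per_slide, colocalization = coloc,
                      multiview = multiview, glomerular = glom),
       truth = sim$truth)
}
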