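#' Simulation configuration for a pseudobulk cohort with planted programs
#'
#' Collects the parameters of the synthetic cohort generator. The generated
#' cohort mirrors the statistical structure of a multi-batch single-cell SLE
#' study: several processing groups, case/control samples, per-cell-type
#' pseudobulk count views driven by latent factor programs, and clinical
#' metadata (SLEDAI, age, sex, ancestry) coupled to program activity.
#'
#' Exactly one planted factor (the "multicellular" program, factor 1) loads on
#' every cell type and is shifted by `disease_effect` standard-deviation units
#' in cases; exactly one (factor 2) is restricted to
#' `restricted_factor_celltype`.
#'
#' @param n_groups number of processing groups (batches).
#' @param samples_per_group samples per group; half cases, half controls.
#' @param n_celltypes number of cell types (views).
#' @param genes_per_celltype genes per view.
#' @param n_factors_true number of planted latent factors (>= 2).
#' @param disease_effect shift of the multicellular program score in cases, in
#'   SD units of the score.
#' @param restricted_factor_celltype cell type carrying the restricted factor;
#'   default the first cell type.
#' @param noise_sd SD of lognormal noise on the linear predictor (> 0).
#' @param composition_shift tilt of case cell-type composition toward the
#'   first cell type (log-scale units).
#' @param seed integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3L, samples_per_group = 20L,
                       n_celltypes = 5L, genes_per_celltype = 300L,
                       n_factors_true = 2L, disease_effect = 1.5,
                       restricted_factor_celltype = NULL,
                       noise_sd = 0.3, composition_shift = 0.5,
                       seed = 1L) {
  counts <- c(n_groups = n_groups, samples_per_group = samples_per_group,
              n_celltypes = n_celltypes,
              genes_per_celltype = genes_per_celltype,
              n_factors_true = n_factors_true)
  if (any(counts < 1)) .stopf("all counts must be >= 1")
  if (noise_sd <= 0) .stopf("noise_sd must be > 0")
  if (n_factors_true < 2) .stopf("need >= 2 planted factors")
  celltypes <- paste0("ct", seq_len(n_celltypes))
  if (is.null(restricted_factor_celltype))
    restricted_factor_celltype <- celltypes[1L]
  if (!restricted_factor_celltype %in% celltypes)
    .stopf("restricted_factor_celltype '%s' not among cell types",
           restricted_factor_celltype)
  structure(list(n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 n_celltypes = as.integer(n_celltypes),
                 genes_per_celltype = as.integer(genes_per_celltype),
                 n_factors_true = as.integer(n_factors_true),
                 disease_effect = disease_effect,
                 restricted_factor_celltype = restricted_factor_celltype,
                 noise_sd = noise_sd,
                 composition_shift = composition_shift,
                 seed = as.integer(seed),
                 celltypes = celltypes),
            class = "sim_config")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

#' Generate a pseudobulk cohort with planted multicellular programs
#'
#' Draws per-cell-type sample-by-gene count views from a Poisson model around
#' an exponentiated linear predictor `baseline + loadings %*% scores + noise`.
#' Factor 1 loads on all cell types and its score is shifted by
#' `cfg$disease_effect` in cases; factor 2 loads only on
#' `cfg$restricted_factor_celltype`. SLEDAI is a clipped, rounded linear
#' function of the multicellular score in cases (0-19 integers).
#'
#' @param cfg a [sim_config()].
#' @return A list with components `cohort` (a `pseudobulk_cohort`, see
#'   [aggregate_pseudobulk()]) and `truth` (true scores, loadings and
#'   composition parameters).
#' @export
generate_pseudobulk_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_groups * cfg$samples_per_group
    fnames <- paste0("true_f", seq_len(cfg$n_factors_true))
    samples <- sprintf("S%03d", seq_len(n))
    group <- rep(paste0("g", seq_len(cfg$n_groups)),
                 each = cfg$samples_per_group)
    condition <- rep(rep(c("case", "control"),
                         length.out = cfg$samples_per_group), cfg$n_groups)
    is_case <- condition == "case"

    z <- matrix(rnorm(n * cfg$n_factors_true), n, cfg$n_factors_true,
                dimnames = list(samples, fnames))
    # group-specific score offsets (the only simulated batch effect)
    goff <- matrix(rnorm(cfg$n_groups * cfg$n_factors_true, sd = 0.3),
                   cfg$n_groups, cfg$n_factors_true)
    z <- z + goff[match(group, unique(group)), , drop = FALSE]
    z[, 1L] <- z[, 1L] + ifelse(is_case, cfg$disease_effect, 0)

    loading_scale <- 0.5
    views <- list()
    true_w <- list()
    for (ct in cfg$celltypes) {
      g <- cfg$genes_per_celltype
      genes <- paste0(ct, "_g", seq_len(g))
      W <- matrix(0, g, cfg$n_factors_true, dimnames = list(genes, fnames))
      n_load <- max(10L, round(0.25 * g))
      # factor 1: multicellular, loads in every view
      idx1 <- sample.int(g, n_load)
      W[idx1, 1L] <- sample(c(-1, 1), n_load, TRUE) *
        runif(n_load, 0.5, 1) * loading_scale
      if (ct == cfg$restricted_factor_celltype) {
        idx2 <- sample.int(g, n_load)
        W[idx2, 2L] <- sample(c(-1, 1), n_load, TRUE) *
          runif(n_load, 0.5, 1) * loading_scale
      }
      if (cfg$n_factors_true > 2L) {
        for (f in 3:cfg$n_factors_true) {
          if (runif(1) < 0.5) next
          idxf <- sample.int(g, n_load)
          W[idxf, f] <- sample(c(-1, 1), n_load, TRUE) *
            runif(n_load, 0.5, 1) * loading_scale
        }
      }
      baseline <- runif(g, log(20), log(200))
      eta <- matrix(baseline, n, g, byrow = TRUE) + z %*% t(W) +
        matrix(rnorm(n * g, sd = cfg$noise_sd), n, g)
      counts <- matrix(rpois(n * g, exp(eta)), n, g,
                       dimnames = list(samples, genes))
      views[[ct]] <- counts
      true_w[[ct]] <- W
    }

    # cell-type composition with a case tilt toward the first cell type
    comp_logit <- matrix(rnorm(n * cfg$n_celltypes, sd = 0.3),
                         n, cfg$n_celltypes)
    comp_logit[, 1L] <- comp_logit[, 1L] +
      ifelse(is_case, cfg$composition_shift, 0)
    props <- exp(comp_logit) / rowSums(exp(comp_logit))
    total_cells <- 2000L
    cell_counts <- t(vapply(seq_len(n), function(i)
      c(stats::rmultinom(1L, total_cells, props[i, ])), integer(cfg$n_celltypes)))
    dimnames(cell_counts) <- list(samples, cfg$celltypes)
    cell_counts <- t(cell_counts)  # celltype x sample

    sledai <- ifelse(is_case,
                     pmin(19L, pmax(0L, round(5 + 2.2 * (z[, 1L] -
                       cfg$disease_effect * mean(is_case)) + rnorm(n, sd = 1.2)))),
                     pmin(2L, pmax(0L, round(rnorm(n, 0.3, 0.5)))))
    meta <- data.frame(sample_id = samples, patient_id = samples,
                       condition = condition, group = group,
                       age = round(runif(n, 18, 70)),
                       sex = sample(c("F", "M"), n, TRUE, prob = c(0.9, 0.1)),
                       ancestry = sample(c("EUR", "AFR", "ASI"), n, TRUE),
                       sledai = as.integer(sledai),
                       stringsAsFactors = FALSE)

    cohort <- new_pseudobulk_cohort(views, meta, cell_counts)
    truth <- list(true_scores = z, true_loadings = true_w,
                  composition_props = props,
                  restricted_factor_celltype = cfg$restricted_factor_celltype,
                  multicellular_factor = fnames[1L],
                  restricted_factor = fnames[2L])
    list(cohort = cohort, truth = truth)
  })
}

#' Generate single cells as convex mixtures of archetypes
#'
#' Each cell is a Dirichlet mixture of `k` archetype coordinates in a
#' `dim`-dimensional embedding, plus isotropic Gaussian noise. The per-patient
#' Dirichlet concentration of archetype 1 is tilted by
#' `exp(coupling * score)`, so patients with high program scores harbor cells
#' closer to archetype 1.
#'
#' @param k number of archetypes (>= 2, <= dim + 1).
#' @param dim embedding dimensionality.
#' @param cells_per_patient cells per patient.
#' @param n_patients number of patients.
#' @param coupling strength of the program-score tilt toward archetype 1.
#' @param noise_sd SD of the isotropic cell noise.
#' @param scores optional per-patient program scores; standard normal draws
#'   when `NULL`.
#' @param seed integer seed.
#' @return A list: `embedding` (cell x dim), `expression` (cell x gene),
#'   `patient` (cell labels), `patient_scores`, and `truth` with
#'   `archetype_coords_true` and the mixture matrix `S`.
#' @export
generate_single_cells <- function(k, dim, cells_per_patient, n_patients,
                                  coupling, noise_sd = 0.1, scores = NULL,
                                  seed = 1L) {
  if (k < 2) .stopf("k must be >= 2")
  if (k > dim + 1) .stopf("k > dim + 1 gives degenerate simplex geometry")
  .with_seed(seed, {
    A <- if (k <= dim) {
      cbind(3 * diag(k), matrix(0, k, dim - k))
    } else {
      rbind(diag(dim), rep((1 - sqrt(1 + dim)) / dim, dim)) * 3
    }
    rownames(A) <- paste0("arch", seq_len(k))
    if (is.null(scores)) scores <- rnorm(n_patients)
    names(scores) <- sprintf("P%03d", seq_len(n_patients))
    n_cells <- cells_per_patient * n_patients
    patient <- rep(names(scores), each = cells_per_patient)
    S <- matrix(0, n_cells, k)
    for (p in seq_len(n_patients)) {
      alpha <- rep(1, k)
      alpha[1L] <- exp(coupling * scores[p])
      rows <- (p - 1L) * cells_per_patient + seq_len(cells_per_patient)
      S[rows, ] <- .rdirichlet(cells_per_patient, alpha)
    }
    X <- S %*% A + matrix(rnorm(n_cells * dim, sd = noise_sd), n_cells, dim)
    rownames(X) <- paste0("cell", seq_len(n_cells))
    n_genes <- max(20L, 5L * dim)
    G <- matrix(rnorm(dim * n_genes, sd = 1 / sqrt(dim)), dim, n_genes)
    expr <- X %*% G +
      matrix(rnorm(n_cells * n_genes, sd = noise_sd), n_cells, n_genes)
    colnames(expr) <- paste0("g", seq_len(n_genes))
    rownames(expr) <- rownames(X)
    list(embedding = X, expression = expr, patient = patient,
         patient_scores = scores,
         truth = list(archetype_coords_true = A, S = S))
  })
}

#' Generate longitudinal visits with program-dependent flare hazard
#'
#' Per-visit program activity follows a patient random effect plus visit
#' noise. Between consecutive visits a flare time is drawn from an
#' exponential hazard `base_hazard * exp(beta_flare * activity)`; a flare
#' triggers an early next visit at the flare date, with a SLEDAI jump >= 4.
#' Expression of planted signature genes scales with activity.
#'
#' @param n_patients number of patients.
#' @param visits_per_patient visits per patient (>= 3).
#' @param beta_flare log-hazard coefficient of program activity.
#' @param base_hazard baseline flare hazard per day.
#' @param n_genes number of expression features (half signature genes).
#' @param seed integer seed.
#' @return A `data.frame` (class `visit_table`): `patient`, `visit`, `day`,
#'   `sledai`, `activity`, `time_since_prev`, `time_to_next`, `event`
#'   (`"flare"`/`"none"`); attributes `expression` (visit x gene z-scores)
#'   and `truth` (signature genes, planted log-hazard).
#' @export
generate_longitudinal <- function(n_patients, visits_per_patient, beta_flare,
                                  base_hazard = 0.003, n_genes = 30L,
                                  seed = 1L) {
  if (visits_per_patient < 3) .stopf("visits_per_patient must be >= 3")
  .with_seed(seed, {
    rows <- list()
    n_sig <- n_genes %/% 2L
    sig_genes <- paste0("sg", seq_len(n_sig))
    genes <- c(sig_genes, paste0("bg", seq_len(n_genes - n_sig)))
    w_sig <- runif(n_sig, 0.6, 1.2)
    expr <- matrix(0, 0, n_genes)
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%03d", p)
      u <- rnorm(1, sd = 0.7)
      day <- 0
      sled <- max(0L, round(rnorm(1, 0.8, 0.6)))
      for (v in seq_len(visits_per_patient)) {
        act <- u + rnorm(1, sd = 0.7)
        gap <- round(runif(1, 30, 90))
        flare <- FALSE
        t_next <- gap
        if (v < visits_per_patient) {
          tf <- rexp(1, rate = base_hazard * exp(beta_flare * act))
          if (tf < gap) {
            flare <- TRUE
            t_next <- max(1, round(tf))
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient = pid, visit = v, day = day, sledai = sled,
          activity = act,
          time_to_next = if (v < visits_per_patient) t_next else NA_real_,
          event = if (v < visits_per_patient && flare) "flare" else "none",
          stringsAsFactors = FALSE)
        e <- c(w_sig * act + rnorm(n_sig, sd = 0.6),
               rnorm(n_genes - n_sig))
        expr <- rbind(expr, e)
        sled <- if (flare) sled + 4L + stats::rpois(1, 2) else
          max(0L, sled + sample(-1:1, 1))
        day <- day + t_next
      }
    }
    out <- do.call(rbind, rows)
    out$time_since_prev <- ave(out$day, out$patient,
                               FUN = function(d) c(NA, diff(d)))
    rownames(out) <- paste(out$patient, out$visit, sep = "_v")
    dimnames(expr) <- list(rownames(out), genes)
    attr(out, "expression") <- expr
    attr(out, "truth") <- list(signature_genes = sig_genes,
                               signature_weights = setNames(w_sig, sig_genes),
                               flare_log_hazard = beta_flare)
    class(out) <- c("visit_table", "data.frame")
    out
  })
}

#' Generate spatial slides with immune/program co-elevated niches
#'
#' Each slide is a regular lattice of spots with disk-shaped "glomerular"
#' niches. On case slides both the program score and the immune abundance are
#' elevated inside niches with strength `coloc` (plus Gaussian noise); on
#' control slides both are independent noise.
#'
#' @param n_slides number of slides (alternating case/control).
#' @param grid integer vector `c(rows, cols)` of the spot lattice.
#' @param niche_radius niche radius in lattice units.
#' @param coloc elevation of program and immune signals inside niches.
#' @param noise_sd SD of the spot-level noise.
#' @param n_niches niches per slide.
#' @param seed integer seed.
#' @return A list of `spatial_slide` objects: `coords`, `features` (named
#'   list with `program` and `abundance` spot x cell-type matrix),
#'   `compositions`, `annotations` (glomerular / neighbor flags), `condition`.
#' @export
generate_spatial <- function(n_slides = 4L, grid = c(20L, 20L),
                             niche_radius = 2.5, coloc = 1, noise_sd = 0.5,
                             n_niches = 3L, seed = 1L) {
  if (prod(grid) < 4 * niche_radius^2)
    .stopf("grid too small to contain a niche of radius %g", niche_radius)
  .with_seed(seed, {
    lapply(seq_len(n_slides), function(s) {
      condition <- if (s %% 2L == 1L) "case" else "control"
      coords <- as.matrix(expand.grid(x = seq_len(grid[1L]),
                                      y = seq_len(grid[2L])))
      n <- nrow(coords)
      rownames(coords) <- paste0("spot", seq_len(n))
      centers <- cbind(runif(n_niches, 1 + niche_radius, grid[1L] - niche_radius),
                       runif(n_niches, 1 + niche_radius, grid[2L] - niche_radius))
      dmin <- apply(centers, 1L, function(ce)
        sqrt((coords[, 1L] - ce[1L])^2 + (coords[, 2L] - ce[2L])^2))
      glom <- apply(dmin <= niche_radius, 1L, any)
      neighbor <- apply(dmin <= niche_radius + 2, 1L, any) & !glom
      elev <- if (condition == "case") coloc * as.numeric(glom) else 0
      program <- elev + rnorm(n, sd = noise_sd)
      immune <- elev + rnorm(n, sd = noise_sd)
      other <- matrix(rnorm(2L * n, sd = noise_sd), n, 2L)
      abundance <- cbind(IMM = immune, EPI = other[, 1L], STR = other[, 2L])
      rownames(abundance) <- rownames(coords)
      raw <- exp(cbind(IMM = immune, EPI = other[, 1L], STR = other[, 2L]))
      compositions <- raw / rowSums(raw)
      rownames(compositions) <- rownames(coords)
      structure(list(coords = coords,
                     features = list(program = setNames(program,
                                                        rownames(coords)),
                                     abundance = abundance),
                     compositions = compositions,
                     annotations = data.frame(spot = rownames(coords),
                                              glomerular = glom,
                                              neighbor = neighbor,
                                              stringsAsFactors = FALSE),
                     condition = condition,
                     truth = list(planted_moran_sign =
                                    if (coloc > 0) "positive" else "none",
                                  niche_centers = centers)),
                class = "spatial_slide")
    })
  })
}

#' Generate prior-knowledge tables over a gene universe
#'
#' Emits a ligand-receptor resource, a cytokine dictionary of weighted gene
#' sets keyed by (cytokine, cell type), and a blood-protein list with
#' elevated-in-cases flags. When `planted_set` is supplied, a planted
#' "IFN-like" cytokine whose weights equal the planted program's top loadings
#' is included for every cell type, and its genes are added to the elevated
#' protein list.
#'
#' @param genes character vector, the cohort gene universe.
#' @param celltypes character vector of cell types for the dictionary.
#' @param n_lr number of ligand-receptor rows.
#' @param n_cytokines number of random background cytokines.
#' @param n_proteins number of blood-protein rows (0 allowed).
#' @param planted_set optional named numeric vector of gene weights defining
#'   the planted IFN-like cytokine.
#' @param seed integer seed.
#' @return A list: `lr` (data.frame ligand/receptor), `cytokines` (named list
#'   of weighted sets keyed `"cytokine|celltype"`), `proteins` (data.frame
#'   gene/elevated).
#' @export
generate_priors <- function(genes, celltypes, n_lr = 50L, n_cytokines = 10L,
                            n_proteins = 40L, planted_set = NULL, seed = 1L) {
  if (n_lr < 1 || n_cytokines < 1) .stopf("counts must be >= 1")
  .with_seed(seed, {
    pick <- function(n) sample(genes, n, replace = length(genes) < n)
    lig <- pick(n_lr)
    rec <- pick(n_lr)
    lr <- unique(data.frame(ligand = lig, receptor = rec,
                            stringsAsFactors = FALSE))
    while (nrow(lr) < n_lr) {
      lr <- unique(rbind(lr, data.frame(ligand = pick(1L), receptor = pick(1L),
                                        stringsAsFactors = FALSE)))
    }
    lr <- lr[seq_len(n_lr), ]
    rownames(lr) <- NULL

    cyt <- list()
    for (i in seq_len(n_cytokines)) {
      for (ct in celltypes) {
        gs <- pick(min(20L, length(genes)))
        cyt[[paste0("CK", i, "|", ct)]] <- setNames(rnorm(length(gs)), gs)
      }
    }
    if (!is.null(planted_set)) {
      for (ct in celltypes) cyt[[paste0("CK_IFN|", ct)]] <- planted_set
    }

    proteins <- if (n_proteins > 0) {
      pg <- pick(n_proteins)
      data.frame(gene = pg, elevated = runif(n_proteins) < 0.6,
                 stringsAsFactors = FALSE)
    } else data.frame(gene = character(), elevated = logical())
    if (!is.null(planted_set) && nrow(proteins) > 0) {
      top <- names(sort(abs(planted_set), decreasing = TRUE))
      top <- head(top, 5L)
      add <- setdiff(top, proteins$gene)
      if (length(add))
        proteins <- rbind(proteins,
                          data.frame(gene = add, elevated = TRUE,
                                     stringsAsFactors = FALSE))
      proteins$elevated[proteins$gene %in% top] <- TRUE
    }
    list(lr = lr, cytokines = cyt, proteins = proteins)
  })
}
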