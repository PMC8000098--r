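#' Experiment configuration
#'
#' Assembles and validates the configuration of a replicated simulation
#' experiment. The `paper` preset mirrors the full-scale study conditions
#' (200,000 HD markers, 2000 founder haplotypes, 36 replicates per QTN
#' model); the `desk` preset is the reduced-scale counterpart used for
#' testing and routine runs: 20 chromosomes with 1000 HD markers each (MD
#' and LD as the same 0.30 / 0.003 fractions of HD), 600 founder haplotypes,
#' and a shorter Wright-Fisher burn-in with a proportionally raised mutation
#' rate so that population-scaled diversity (4 Ne mu L) still supplies the
#' marker panels. Cohort structure (150-doe/150-male cohorts, 1500-doe
#' candidate cohort) is identical in both presets.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param qtn_models subset of `c("QTN_44", "QTN_5")`.
#' @param scenarios subset of [scenario_ids()].
#' @param n_replicates replicates per QTN model.
#' @param seed root seed; every stage derives its own stream from it.
#' @param out_dir optional output directory for CSV results.
#' @param ... overrides for any of the list fields (e.g. `hd_per_chromosome`,
#'   `genome`, `scheme`, `md_fraction`, `window`, `switch_penalty`).
#' @return validated `experiment_config` list.
#' @export
experiment_config <- function(scale = c("desk", "paper"),
                              qtn_models = c("QTN_44", "QTN_5"),
                              scenarios = scenario_ids(),
                              n_replicates = 4, seed = 1L, out_dir = NULL,
                              ...) {
  scale <- match.arg(scale)
  base <- if (scale == "desk") {
    list(
      genome = list(n_founder_haplotypes = 600,
                    n_sites_per_chromosome = 5000,
                    mutation_rate_per_bp = 1e-8,
                    effective_size_schedule =
                      data.frame(generations = c(250, 100),
                                 ne = c(250, 100))),
      hd_per_chromosome = 1000)
  } else {
    list(genome = list(), hd_per_chromosome = 10000)
  }
  cfg <- list(scale = scale,
              genome = base$genome,
              scheme = list(),
              hd_per_chromosome = base$hd_per_chromosome,
              md_fraction = 0.30, ld_fraction = 0.003,
              qtn_models = qtn_models, scenarios = scenarios,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed), out_dir = out_dir,
              window = 5L, switch_penalty = 1, call_margin = 0.1,
              blend = 0.05, selected_fraction = 0.10)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
}

#' Validate and normalise an experiment configuration
#'
#' Fills defaults and reports all contradictions together: unknown scenarios
#' or QTN models, panel-nesting violations (`ld_fraction > md_fraction`),
#' and desk-preset runtime guards (at most 2000 HD markers per chromosome
#' and 8 replicates). A `paper`-scale run with many replicates is accepted
#' with a runtime warning.
#'
#' @param cfg an `experiment_config` list (possibly partial).
#' @return the normalised config, or an error listing every violation.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  if (!all(cfg$qtn_models %in% c("QTN_44", "QTN_5"))) {
    errs <- c(errs, paste("unknown QTN model:",
                          paste(setdiff(cfg$qtn_models,
                                        c("QTN_44", "QTN_5")),
                                collapse = ", ")))
  }
  if (!all(cfg$scenarios %in% scenario_ids())) {
    errs <- c(errs, paste("unknown scenario:",
                          paste(setdiff(cfg$scenarios, scenario_ids()),
                                collapse = ", ")))
  }
  if (cfg$ld_fraction > cfg$md_fraction) {
    errs <- c(errs, sprintf(
      "panel nesting violated: ld_fraction (%g) > md_fraction (%g)",
      cfg$ld_fraction, cfg$md_fraction))
  }
  if (cfg$md_fraction > 1) {
    errs <- c(errs, "md_fraction must be <= 1")
  }
  if (cfg$scale == "desk") {
    if (cfg$hd_per_chromosome > 2000) {
      errs <- c(errs, "desk preset: hd_per_chromosome must be <= 2000")
    }
    if (cfg$n_replicates > 8) {
      errs <- c(errs, "desk preset: n_replicates must be <= 8")
    }
  } else if (cfg$n_replicates > 8) {
    warning("paper-scale run with ", cfg$n_replicates,
            " replicates: expect a long runtime")
  }
  if (length(errs)) {
    stop("invalid experiment configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- "experiment_config"
  cfg
}

.qtn_per_chromosome <- function(model) {
  switch(model, QTN_44 = 44L, QTN_5 = 5L,
         stop("unknown QTN model: ", model))
}

#' Pedigree-BLUP evaluator for within-program selection
#'
#' Factory for the selection callback used in the BLUP phase of
#' [run_program()]: an animal-model BLUP on the pedigree window of the most
#' recent `window` generations, using all doe records in the window
#' (a doe's first-parity record is available when her cohort is selected).
#'
#' @param lambda variance ratio sigma_e2 / sigma_a2.
#' @param window generations retained in the MME.
#' @return `function(ped, ctx)` returning EBVs for `ctx$cohort_ids`.
#' @export
make_blup_evaluator <- function(lambda, window = 5L) {
  function(ped, ctx) {
    gmax <- max(ped$generation)
    sub <- ped[ped$generation > gmax - window, ]
    sub$sire[!(sub$sire %in% sub$id)] <- 0L
    sub$dam[!(sub$dam %in% sub$id)] <- 0L
    Ainv <- a_inverse(sub)
    rec <- which(!is.na(sub$phenotype))
    sol <- solve_mme(sub$phenotype[rec], rec, Ainv, lambda, "BLUP")
    unname(sol$ebv[match(ctx$cohort_ids, sub$id)])
  }
}

#' Genomic evaluator for the genomic-phase matings
#'
#' Factory for the callback that picks sires in the two genomic generations:
#' single-step GBLUP on the same pedigree window, with the current cohort
#' genotyped at the (unmasked) HD markers. All scenarios of a replicate share
#' the pedigree this produces; masking only happens afterwards.
#'
#' @param lambda variance ratio sigma_e2 / sigma_a2.
#' @param hd_idx global site indices of the HD markers.
#' @param window generations retained in the MME.
#' @param blend weight of A22 in the blended G.
#' @return `function(ped, ctx)` returning EBVs for `ctx$cohort_ids`.
#' @export
make_genomic_evaluator <- function(lambda, hd_idx, window = 5L,
                                   blend = 0.05) {
  function(ped, ctx) {
    gmax <- max(ped$generation)
    sub <- ped[ped$generation > gmax - window, ]
    sub$sire[!(sub$sire %in% sub$id)] <- 0L
    sub$dam[!(sub$dam %in% sub$id)] <- 0L
    A <- tabular_a(sub)
    Ainv <- a_inverse(sub, F = diag(A) - 1)
    gidx <- match(ctx$cohort_ids, sub$id)
    dos <- ctx$get_dosage(ctx$cohort_ids, hd_idx)
    qc <- qc_genotypes(dos)
    dosq <- dos[qc$keep_animals, qc$keep_sites, drop = FALSE]
    gidx <- gidx[qc$keep_animals]
    A22 <- A[gidx, gidx]
    G <- g_matrix(dosq, a22 = A22, blend = blend)
    Hinv <- h_inverse(Ainv, G, A22, gidx)
    rec <- which(!is.na(sub$phenotype))
    sol <- solve_mme(sub$phenotype[rec], rec, Hinv, lambda, "ssGBLUP")
    unname(sol$ebv[match(ctx$cohort_ids, sub$id)])
  }
}

# flatten + restrict the pool to the HD-panel and QTN columns; remaps the
# panel and architecture indices into the restricted coordinates
.restrict_to_markers <- function(flat, panel, arch) {
  keep <- sort(union(panel$hd, arch$qtn_idx))
  flat_r <- list(hap = flat$hap[, keep, drop = FALSE],
                 site_chr = flat$site_chr[keep],
                 site_bp = flat$site_bp[keep],
                 site_cM = flat$site_cM[keep],
                 freq = flat$freq[keep])
  flat_r$chr_start <- match(unique(flat_r$site_chr), flat_r$site_chr)
  flat_r$chr_len_cM <- flat$chr_len_cM[unique(flat_r$site_chr)]
  panel_r <- panel
  panel_r$hd <- match(panel$hd, keep)
  panel_r$md <- match(panel$md, keep)
  panel_r$ld <- match(panel$ld, keep)
  arch_r <- arch
  arch_r$qtn_idx <- match(arch$qtn_idx, keep)
  list(flat = flat_r, panel = panel_r, arch = arch_r, keep = keep)
}

# shared per-replicate evaluation context: the Table-2 data layout
# (pedigree of the last six generations, candidate does' phenotypes
# excluded, generation-28 males dropped) plus the relationship structures
.prepare_evaluation <- function(sim, arch) {
  ped <- sim$ped
  g_last <- max(ped$generation)
  keep <- ped$generation >= g_last - 5L &
    !(ped$generation == g_last & ped$sex == "M")
  pe <- ped[keep, ]
  pe$sire[!(pe$sire %in% pe$id)] <- 0L
  pe$dam[!(pe$dam %in% pe$id)] <- 0L
  A <- tabular_a(pe)
  F <- diag(A) - 1
  Ainv <- a_inverse(pe, F = F)
  rec <- which(!is.na(pe$phenotype) & pe$generation < g_last)
  cand <- which(pe$generation == g_last)
  list(ped = pe, A = A, Ainv = Ainv, F = F,
       y = pe$phenotype[rec], record_rows = rec,
       cand_rows = cand, cand_ids = pe$id[cand], cand_tbv = pe$tbv[cand],
       lambda = arch$sigma_e2 / arch$sigma_a2, g_last = g_last)
}

#' Evaluate one genotyping scenario on a simulated replicate
#'
#' Applies the scenario's mask, runs the imputation engine, assembles the
#' scenario's genotyped set (male ancestors always; female ancestors only
#' where the scenario uses their genotypes; candidates' imputed dosages),
#' performs QC, builds the blended G and the single-step H-inverse, solves
#' the animal model, and computes the endpoint metrics on the candidate
#' does. The `BLUP` scenario skips masking and imputation and solves the
#' pedigree-only model.
#'
#' @param scenario_id scenario to evaluate.
#' @param sim result of [run_program()].
#' @param panel restricted `marker_panel`.
#' @param flat restricted flattened pool.
#' @param arch scaled architecture (restricted indices).
#' @param ev shared evaluation context (internal; built once per replicate).
#' @param cfg `experiment_config`.
#' @param rep_seed replicate stream seed (shared by all scenarios of the
#'   replicate so the half-progeny split matches between S3 and S3_A).
#' @param imputation_only skip the genomic evaluation and return only the
#'   imputation metrics and cost (accuracy columns NA).
#' @return list with `outcome` (one-row data.frame) and `ebv` (candidate
#'   EBVs; NULL with `imputation_only`).
#' @export
evaluate_scenario <- function(scenario_id, sim, panel, flat, arch, ev, cfg,
                              rep_seed, imputation_only = FALSE) {
  spec <- scenario_spec(scenario_id)
  n_cand <- length(ev$cand_ids)
  n_sel <- max(1L, round(cfg$selected_fraction * n_cand))
  mean_ia <- sd_ia <- mean_yield <- NA_real_

  if (scenario_id == "BLUP") {
    sol <- solve_mme(ev$y, ev$record_rows, ev$Ainv, ev$lambda, "BLUP")
    ebv_cand <- unname(sol$ebv[ev$cand_rows])
    cost <- 0
  } else {
    masked <- apply_scenario(spec, sim$ped, panel, sim$get_dosage,
                             seed = derive_seed(rep_seed, "progeny_split"))
    map_hd <- list(site_cM = flat$site_cM[panel$hd],
                   chr_start = match(unique(flat$site_chr[panel$hd]),
                                     flat$site_chr[panel$hd]),
                   chr_len_cM = flat$chr_len_cM)
    imp <- run_imputation(spec, masked, sim$ped, map_hd,
                          freq = flat$freq[panel$hd],
                          switch_penalty = cfg$switch_penalty,
                          call_margin = cfg$call_margin)
    imp_ids <- as.integer(rownames(imp$dosage))
    true_cand <- sim$get_dosage(imp_ids, panel$hd)
    ia <- imputation_accuracy(true_cand, imp$dosage, imp$untyped_cols)
    yld <- genotype_yield(imp$hard, imp$untyped_cols)
    mean_ia <- ia$mean; sd_ia <- ia$sd; mean_yield <- yld$mean
    rm(true_cand)
    roles <- masked$roles
    counts <- table(roles$role)
    cost <- scenario_cost(
      spec,
      role_counts = c(grand_dams = counts[["grand_dams"]],
                      grand_sires = counts[["grand_sires"]],
                      dams = counts[["dams"]], sires = counts[["sires"]],
                      progeny = counts[["progeny"]]))
    if (imputation_only) {
      return(list(outcome = data.frame(
        scenario = scenario_id, mean_ia = mean_ia, sd_ia = sd_ia,
        mean_yield = mean_yield, accuracy = NA_real_, response = NA_real_,
        pct_correct = NA_real_, cost = cost), ebv = NULL))
    }

    # genotyped set fed to G (Table-2 discipline)
    male_anc <- roles$id[roles$role %in% c("grand_sires", "sires")]
    fem_anc <- if (isTRUE(spec$female_ancestors_in_G)) {
      roles$id[roles$role %in% c("grand_dams", "dams")]
    } else {
      integer(0)
    }
    anc_ids <- c(male_anc, fem_anc)
    anc_dos <- sim$get_dosage(anc_ids, panel$hd)
    dos <- rbind(anc_dos, imp$dosage)
    gids <- c(anc_ids, imp_ids)
    rm(imp, masked, anc_dos)
    gc(FALSE)

    # QC on the fractional dosage matrix that feeds G: imputation emits a
    # dosage everywhere, so the call-rate filters only bite on genuinely
    # missing entries and the MAF filter does the work
    qc <- qc_genotypes(dos)
    dosq <- dos[qc$keep_animals, qc$keep_sites, drop = FALSE]
    gids_q <- gids[qc$keep_animals]
    gpos <- match(gids_q, ev$ped$id)
    stopifnot(!anyNA(gpos))
    A22 <- ev$A[gpos, gpos]
    G <- g_matrix(dosq, a22 = A22, blend = cfg$blend)
    Hinv <- h_inverse(ev$Ainv, G, A22, gpos)
    sol <- solve_mme(ev$y, ev$record_rows, Hinv, ev$lambda, "ssGBLUP")
    ebv_cand <- unname(sol$ebv[ev$cand_rows])
    # non-genotyped candidates of the half-genotyped scenario are ranked by
    # their parent-average EBV
    if (spec$progeny_split < 1 && !spec$whole_genome) {
      ng <- setdiff(ev$cand_ids, imp_ids)
      if (length(ng)) {
        pa <- parent_average_ebv(ev$ped, sol$ebv, ng)
        ebv_cand[match(ng, ev$cand_ids)] <- pa
      }
    }
  }
  outcome <- data.frame(
    scenario = scenario_id,
    mean_ia = mean_ia, sd_ia = sd_ia, mean_yield = mean_yield,
    accuracy = gebv_accuracy(ebv_cand, ev$cand_tbv),
    response = selection_response(ev$cand_tbv, ebv_cand, n_sel,
                                  ids = ev$cand_ids),
    pct_correct = percent_correctly_selected(ebv_cand, ev$cand_tbv, n_sel,
                                             ids = ev$cand_ids),
    cost = cost)
  list(outcome = outcome, ebv = stats::setNames(ebv_cand, ev$cand_ids))
}

#' Run one simulated replicate
#'
#' Full chain for one replicate of one QTN model: founder genomes, trait
#' architecture (QTNs, effects, variance scaling on the founder diploids),
#' marker panels, the breeding program (pedigree BLUP selection, then the
#' genomic phase), and the per-scenario masking / imputation / evaluation.
#' All scenarios share the identical pedigree, genotypes and phenotypes;
#' only masking and evaluation differ.
#'
#' @param qtn_model `"QTN_44"` or `"QTN_5"`.
#' @param cfg an [experiment_config()].
#' @param seed replicate seed (derive from the root seed).
#' @return list with `outcomes` (one row per scenario), `sim`, `panel`,
#'   `flat` (restricted pool), `arch`, `ev`.
#' @export
run_replicate <- function(qtn_model, cfg, seed) {
  qpc <- .qtn_per_chromosome(qtn_model)
  gargs <- cfg$genome
  gargs$seed <- derive_seed(seed, "genome")
  gcfg <- do.call(genome_config, gargs)
  pool <- simulate_founders(gcfg, min_segregating_per_chromosome =
                              cfg$hd_per_chromosome + qpc)
  flat <- flatten_pool(pool)
  arch <- sample_qtns(flat, qpc, seed = derive_seed(seed, "qtn"))
  arch <- sample_effects(arch, seed = derive_seed(seed, "effects"))
  panel <- build_panels(flat, cfg$hd_per_chromosome, cfg$md_fraction,
                        cfg$ld_fraction, qtn_idx = arch$qtn_idx,
                        seed = derive_seed(seed, "panels"))
  r <- .restrict_to_markers(flat, panel, arch)
  flat <- r$flat; panel <- r$panel; arch <- r$arch
  # founder diploids for variance scaling: pool haplotypes paired in order
  n_hap <- nrow(flat$hap)
  odd <- seq(1L, n_hap, 2L)
  fdos <- .dosage_from_gametes(flat$hap[odd, arch$qtn_idx, drop = FALSE],
                               flat$hap[odd + 1L, arch$qtn_idx,
                                        drop = FALSE])
  arch <- scale_variances(arch, fdos)
  scheme <- do.call(scheme_config, cfg$scheme)
  lambda <- arch$sigma_e2 / arch$sigma_a2
  sim <- run_program(flat, arch, scheme,
                     evaluator = make_blup_evaluator(lambda, cfg$window),
                     genomic_evaluator =
                       make_genomic_evaluator(lambda, panel$hd, cfg$window,
                                              cfg$blend),
                     seed = derive_seed(seed, "program"))
  ev <- .prepare_evaluation(sim, arch)
  rows <- lapply(cfg$scenarios, function(sc)
    evaluate_scenario(sc, sim, panel, flat, arch, ev, cfg, seed)$outcome)
  outcomes <- do.call(rbind, rows)
  outcomes$qtn_model <- qtn_model
  list(outcomes = outcomes, sim = sim, panel = panel, flat = flat,
       arch = arch, ev = ev)
}

#' Run the replicated experiment
#'
#' Loops over QTN models and replicates (each replicate fully seeded from
#' the root seed), collects per-scenario outcomes, and writes
#' `outcomes.csv`, `summary.csv` and `costs.csv` to `cfg$out_dir` when set.
#' A failed replicate is logged and skipped; the others continue.
#'
#' @param cfg an [experiment_config()].
#' @param keep_sims keep the heavyweight per-replicate simulation objects
#'   (default drops them, returning outcomes only).
#' @return list with `outcomes` (per replicate x scenario), `summary` (from
#'   [summarize_outcomes()]) and `costs`.
#' @export
run_experiment <- function(cfg, keep_sims = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  all_rows <- list()
  sims <- list()
  for (model in cfg$qtn_models) {
    for (rep in seq_len(cfg$n_replicates)) {
      rep_seed <- derive_seed(cfg$seed, "replicate", model, rep)
      message(sprintf("[%s] replicate %d/%d (seed %d)", model, rep,
                      cfg$n_replicates, rep_seed))
      res <- tryCatch(run_replicate(model, cfg, rep_seed),
                      error = function(e) {
                        message("  replicate failed: ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      out <- res$outcomes
      out$replicate <- rep
      all_rows[[length(all_rows) + 1L]] <- out
      if (keep_sims) sims[[paste(model, rep, sep = "_")]] <- res
      rm(res)
      gc(FALSE)
    }
  }
  if (!length(all_rows)) stop("run_experiment: every replicate failed")
  outcomes <- do.call(rbind, all_rows)
  summ <- summarize_outcomes(outcomes)
  costs <- data.frame(scenario = setdiff(scenario_ids(), "BLUP"))
  costs$cost_eur <- vapply(costs$scenario, scenario_cost, numeric(1))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(outcomes, file.path(cfg$out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$summary, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(costs, file.path(cfg$out_dir, "costs.csv"),
                     row.names = FALSE)
  }
  res <- list(outcomes = outcomes, summary = summ, costs = costs)
  if (keep_sims) res$sims <- sims
  res
}
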