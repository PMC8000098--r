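# Memoised fixtures shared across test files. Everything is generated in
# code from fixed seeds; the first accessor call pays the simulation cost.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small founder pool: 3 chromosomes, 80 haplotypes, enough segregating
# sites for a 120-marker HD panel plus QTNs
tiny_pool <- function() {
  memo_fixture("tiny_pool", function() {
    simulate_founders(genome_config(
      n_chromosomes = 3, n_founder_haplotypes = 80,
      n_sites_per_chromosome = 1200, mutation_rate_per_bp = 1e-8,
      effective_size_schedule = data.frame(generations = c(60, 30),
                                           ne = c(60, 40)),
      seed = 42), min_segregating_per_chromosome = 130L)
  })
}

tiny_cfg <- function(scenarios = scenario_ids()) {
  experiment_config(
    scale = "desk", n_replicates = 1, seed = 11,
    genome = list(n_chromosomes = 3, n_founder_haplotypes = 80,
                  n_sites_per_chromosome = 1200,
                  mutation_rate_per_bp = 1e-8,
                  effective_size_schedule =
                    data.frame(generations = c(60, 30), ne = c(60, 40))),
    hd_per_chromosome = 120,
    scheme = list(base_does = 18, base_sires = 7,
                  selected_does_per_gen = 8, selected_sires_per_gen = 4,
                  cohort_females = 20, cohort_males = 20,
                  blup_generations = 3, genomic_generations = 2,
                  final_females = 100, final_males = 100,
                  random_mating_generations = 3),
    scenarios = scenarios)
}

# one fully evaluated tiny replicate (all scenarios), reused by the
# scenario, imputation and metric tests
tiny_replicate <- function() {
  memo_fixture("tiny_replicate", function() {
    run_replicate("QTN_5", tiny_cfg(), seed = 99)
  })
}

# a tiny breeding-program run that keeps every generation's gametes, for
# Mendelian-consistency and selection checks
tiny_world <- function() {
  memo_fixture("tiny_world", function() {
    cfg <- tiny_cfg("BLUP")
    gargs <- cfg$genome
    gargs$seed <- 1L
    pool <- simulate_founders(do.call(genome_config, gargs),
                              min_segregating_per_chromosome = 125L)
    flat <- flatten_pool(pool)
    arch <- sample_qtns(flat, 5L, seed = 2)
    arch <- sample_effects(arch, seed = 3)
    panel <- build_panels(flat, 120, qtn_idx = arch$qtn_idx, seed = 4)
    r <- rabbitGS:::.restrict_to_markers(flat, panel, arch)
    flat <- r$flat; panel <- r$panel; arch <- r$arch
    odd <- seq(1L, nrow(flat$hap), 2L)
    fdos <- rabbitGS:::.dosage_from_gametes(
      flat$hap[odd, arch$qtn_idx, drop = FALSE],
      flat$hap[odd + 1L, arch$qtn_idx, drop = FALSE])
    arch <- scale_variances(arch, fdos)
    scheme <- do.call(scheme_config, cfg$scheme)
    lambda <- arch$sigma_e2 / arch$sigma_a2
    sim <- run_program(flat, arch, scheme,
                       evaluator = make_blup_evaluator(lambda),
                       seed = 7, keep_gametes = "all")
    list(pool = pool, flat = flat, arch = arch, panel = panel,
         scheme = scheme, sim = sim, founder_dosages = fdos)
  })
}

# genetic map of a single synthetic chromosome with equally spaced markers
toy_map <- function(n_sites, len_cM = 100) {
  list(site_cM = seq(0.5, len_cM - 0.5, length.out = n_sites),
       chr_start = 1L, chr_len_cM = len_cM)
}
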