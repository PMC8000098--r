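#' Breeding-scheme configuration
#'
#' Cohort sizes and phase lengths of the simulated maternal-line nucleus:
#' a foundation cohort, `random_mating_generations` of random mating ending in
#' a base population of `base_does` does and `base_sires` sires, then
#' `blup_generations` of truncation selection (top `selected_does_per_gen`
#' does and `selected_sires_per_gen` sires of each 150-doe/150-male cohort,
#' ranked by the evaluator callback), and finally two genomic generations in
#' which the full doe cohort serves as dams and the selected males as sires,
#' ending in a candidate cohort of `final_females` does and `final_males`
#' males. Generations are labelled so that the last three are the 26th-28th.
#'
#' @param base_does,base_sires parents drawn per random-mating generation.
#' @param selected_does_per_gen,selected_sires_per_gen truncation-selected
#'   parents per selection generation.
#' @param cohort_females,cohort_males cohort size per generation.
#' @param blup_generations pedigree-BLUP selection generations.
#' @param genomic_generations generations evaluated genomically at the end.
#' @param final_females,final_males size of the last (candidate) cohort.
#' @param random_mating_generations random-mating generations after foundation.
#' @return an object of class `scheme_config`.
#' @export
scheme_config <- function(base_does = 138, base_sires = 77,
                          selected_does_per_gen = 70,
                          selected_sires_per_gen = 35,
                          cohort_females = 150, cohort_males = 150,
                          blup_generations = 20, genomic_generations = 2,
                          final_females = 1500, final_males = 1500,
                          random_mating_generations = 5) {
  cfg <- as.list(environment())
  cfg <- lapply(cfg, as.integer)
  stopifnot(cfg$base_does <= cfg$cohort_females,
            cfg$base_sires <= cfg$cohort_males,
            cfg$selected_does_per_gen <= cfg$cohort_females,
            cfg$selected_sires_per_gen <= cfg$cohort_males,
            cfg$final_females %% cfg$cohort_females == 0L,
            cfg$final_males %% cfg$cohort_females == 0L)
  class(cfg) <- "scheme_config"
  cfg
}

#' Simulate one meiosis
#'
#' Produces a recombinant gamete from a parent's two haplotypes: crossover
#' counts are Poisson(length_cM / 100) per chromosome, positions uniform on
#' the cM map, no interference (Haldane model), and the starting haplotype is
#' chosen with probability one half.
#'
#' @param h1,h2 the parent's two gametes: raw 0/1 vectors over all sites.
#' @param map genetic map: list with `site_cM`, `chr_start` (1-based global
#'   index of each chromosome's first site) and `chr_len_cM`.
#' @param seed optional integer seed.
#' @return a raw gamete vector.
#' @export
meiosis <- function(h1, h2, map, seed = NULL) {
  stopifnot(length(h1) == length(h2), length(h1) == length(map$site_cM))
  .seed_if(seed)
  .meiosis_genome(as.raw(h1), as.raw(h2), map$site_cM,
                  as.integer(map$chr_start) - 1L, map$chr_len_cM)
}

#' Mate one pair
#'
#' Forms `n_offspring` kits from one dam and one sire (one meiosis per parent
#' per kit, no mutation), splits sexes 1:1 (the extra kit of an odd litter
#' gets `odd_sex`), and computes TBVs and phenotypes via the trait
#' architecture.
#'
#' @param dam,sire lists with elements `pat`, `mat` (raw gamete vectors) and
#'   `sex` ("F"/"M").
#' @param n_offspring kits in the litter.
#' @param map genetic map (see [meiosis()]).
#' @param arch a scaled `trait_architecture` (QTN indices are global site
#'   columns).
#' @param odd_sex sex of the surplus kit when `n_offspring` is odd.
#' @param seed optional integer seed.
#' @return list of offspring, each with `pat`, `mat`, `sex`, `tbv`,
#'   `phenotype`.
#' @export
mate <- function(dam, sire, n_offspring, map, arch, odd_sex = "F",
                 seed = NULL) {
  if (identical(dam$sex, sire$sex)) stop("mate: same-sex pairing")
  if (identical(dam$sex, "M")) stop("mate: dam must be female")
  .seed_if(seed)
  n <- as.integer(n_offspring)
  sexes <- rep(c("F", "M"), length.out = 2L * (n %/% 2L))
  if (n %% 2L == 1L) sexes <- c(sexes, odd_sex)
  sexes <- sexes[seq_len(n)]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- meiosis(sire$pat, sire$mat, map)
    mat <- meiosis(dam$pat, dam$mat, map)
    dos <- as.integer(pat[arch$qtn_idx]) + as.integer(mat[arch$qtn_idx])
    tbv <- true_breeding_value(dos, arch)
    phe <- if (sexes[i] == "F" && is.finite(arch$sigma_e2)) {
      arch$mu + tbv + stats::rnorm(1, sd = sqrt(arch$sigma_e2))
    } else {
      NA_real_
    }
    out[[i]] <- list(pat = pat, mat = mat, sex = sexes[i], tbv = tbv,
                     phenotype = phe)
  }
  out
}

# litter-size allocation: n_kits kits over n_dams dams, as equal as possible,
# remainder to randomly chosen dams
.allocate_litters <- function(n_kits, n_dams) {
  base <- n_kits %/% n_dams
  extra <- n_kits %% n_dams
  sizes <- rep(base, n_dams)
  if (extra > 0) sizes[sample.int(n_dams, extra)] <- base + 1L
  sizes
}

# cohort-level sex vector: per-litter 1:1, odd litters alternate the surplus
# sex so the cohort stays exactly balanced
.litter_sexes <- function(sizes) {
  odd_count <- 0L
  unlist(lapply(sizes, function(n) {
    s <- rep(c("F", "M"), length.out = 2L * (n %/% 2L))
    if (n %% 2L == 1L) {
      odd_count <<- odd_count + 1L
      s <- c(s, if (odd_count %% 2L == 1L) "F" else "M")
    }
    s
  }))
}

#' Run the maternal-line breeding program
#'
#' Executes the full scheme: foundation from founder haplotypes, random
#' mating, `blup_generations` of truncation selection on the callback's EBVs,
#' and the genomic phase (the full doe cohort mated to the genomically
#' selected males) ending in the candidate cohort. Gene drop is mutation-free,
#' so every offspring allele descends from a founder allele.
#'
#' @param flat flattened (optionally restricted) pool; see [flatten_pool()].
#' @param arch a scaled `trait_architecture` (global site indices).
#' @param scheme a [scheme_config()].
#' @param evaluator callback `function(ped, ctx)` returning EBVs (numeric,
#'   one per `ctx$cohort_ids`) used for truncation selection in the BLUP
#'   phase. `ctx` carries `generation`, `cohort_ids` and `get_dosage(ids)`.
#' @param genomic_evaluator callback with the same signature used to pick
#'   sires in the two genomic generations; defaults to `evaluator`.
#' @param seed integer root seed for this run.
#' @param keep_gametes `"genomic"` keeps gametes of the genomically used
#'   generations (the last three); `"all"` keeps every generation (small runs
#'   and tests only).
#' @return list with `ped` (data.frame: id, sire, dam, sex, generation, tbv,
#'   phenotype), `gametes` (per kept generation: ids, pat, mat), `map`,
#'   `generations` (named indices of the phases), and `summary`
#'   (per-generation cohort size and TBV mean/SD).
#' @export
run_program <- function(flat, arch, scheme, evaluator,
                        genomic_evaluator = evaluator, seed = 1L,
                        keep_gametes = c("genomic", "all")) {
  stopifnot(inherits(scheme, "scheme_config"),
            inherits(arch, "trait_architecture"), is.function(evaluator))
  keep_gametes <- match.arg(keep_gametes)
  map <- list(site_cM = flat$site_cM, chr_start = flat$chr_start,
              chr_len_cM = flat$chr_len_cM)
  S <- length(flat$site_cM)
  n_gen_total <- scheme$random_mating_generations + scheme$blup_generations +
    scheme$genomic_generations + 1L
  # label generations so the last three are 26th-28th at default settings
  last_gen <- 28L
  gen_label <- function(g) g + (last_gen - n_gen_total)

  ped <- list()
  gam <- list()      # per generation: list(ids, pat, mat)
  next_id <- 1L

  add_cohort <- function(gen, sire_ids, dam_ids, pat, mat, sexes, seed) {
    ids <- next_id - 1L + seq_along(sexes)
    next_id <<- next_id + length(sexes)
    dos <- .dosage_from_gametes(pat[, arch$qtn_idx, drop = FALSE],
                                mat[, arch$qtn_idx, drop = FALSE])
    tbv <- true_breeding_value(dos, arch)
    phe <- sample_phenotypes(sexes, tbv, arch, seed = seed)
    ped[[length(ped) + 1L]] <<- data.frame(
      id = ids, sire = sire_ids, dam = dam_ids, sex = sexes,
      generation = gen, tbv = tbv, phenotype = phe)
    gam[[as.character(gen)]] <<- list(ids = ids, pat = pat, mat = mat)
    ids
  }
  drop_gametes_before <- function(gen) {
    if (keep_gametes == "all") return(invisible())
    for (nm in names(gam)) {
      g <- as.integer(nm)
      if (g < gen && gen_label(g) < last_gen - 2L) gam[[nm]] <<- NULL
    }
  }
  get_dosage <- function(ids, cols = NULL) {
    out <- matrix(NA_integer_, length(ids), if (is.null(cols)) S else
      length(cols))
    rownames(out) <- as.character(ids)
    for (nm in names(gam)) {
      g <- gam[[nm]]
      hit <- which(ids %in% g$ids)
      if (!length(hit)) next
      r <- match(ids[hit], g$ids)
      pat <- g$pat; mat <- g$mat
      if (!is.null(cols)) {
        pat <- pat[, cols, drop = FALSE]; mat <- mat[, cols, drop = FALSE]
      }
      out[hit, ] <- .dosage_from_gametes(pat[r, , drop = FALSE],
                                         mat[r, , drop = FALSE])
    }
    out
  }

  # ---- foundation: pair founder haplotypes into the first cohort ----------
  n_found <- scheme$cohort_females + scheme$cohort_males
  pairs <- draw_diploid_founders(flat, n_found,
                                 seed = derive_seed(seed, "foundation"))
  pat0 <- flat$hap[pairs[, 1], , drop = FALSE]
  mat0 <- flat$hap[pairs[, 2], , drop = FALSE]
  sex0 <- .litter_sexes(rep(2L, n_found %/% 2L))
  found_ids <- add_cohort(0L, rep(0L, n_found), rep(0L, n_found),
                          pat0, mat0, sex0,
                          seed = derive_seed(seed, "phen", 0L))

  breed <- function(gen, dam_ids, sire_ids_pool, sizes, seed) {
    # dams with litter sizes `sizes`; sires round-robin after shuffling
    set.seed(derive_seed(seed, "mate", gen))
    sires <- sample(sire_ids_pool)
    sire_of_dam <- sires[(seq_along(dam_ids) - 1L) %% length(sires) + 1L]
    off_dam <- rep(dam_ids, sizes)
    off_sire <- rep(sire_of_dam, sizes)
    sexes <- .litter_sexes(sizes)
    prev <- gam[[as.character(gen - 1L)]]
    dr <- match(off_dam, prev$ids)
    sr <- match(off_sire, prev$ids)
    # paternal gamete from the sire's pair, maternal from the dam's
    gp <- .gene_drop(prev$pat, prev$mat, sr - 1L, dr - 1L, map$site_cM,
                     as.integer(map$chr_start) - 1L, map$chr_len_cM)
    add_cohort(gen, off_sire, off_dam, gp$pat, gp$mat, sexes,
               seed = derive_seed(seed, "phen", gen))
  }

  # ---- phase (a): random mating ------------------------------------------
  cur_ids <- found_ids
  g <- 1L
  for (k in seq_len(scheme$random_mating_generations)) {
    set.seed(derive_seed(seed, "random_mating", k))
    pd <- do.call(rbind, ped)
    cur <- pd[pd$id %in% cur_ids, ]
    dams <- sample(cur$id[cur$sex == "F"], scheme$base_does)
    sires <- sample(cur$id[cur$sex == "M"], scheme$base_sires)
    sizes <- .allocate_litters(scheme$cohort_females + scheme$cohort_males,
                               length(dams))
    cur_ids <- breed(g, dams, sires, sizes, seed)
    drop_gametes_before(g)
    g <- g + 1L
  }

  # ---- phase (b): truncation selection on callback EBVs ------------------
  select_top <- function(ids, ebv, k) {
    ids[order(-ebv, ids)][seq_len(k)]
  }
  n_select_gens <- scheme$blup_generations + 1L  # incl. the 25th->26th mating
  for (k in seq_len(n_select_gens)) {
    pd <- do.call(rbind, ped)
    ctx <- list(generation = g - 1L, cohort_ids = cur_ids,
                get_dosage = get_dosage, map = map)
    ebv <- evaluator(pd, ctx)
    stopifnot(length(ebv) == length(cur_ids))
    cur <- pd[match(cur_ids, pd$id), ]
    dams <- select_top(cur$id[cur$sex == "F"], ebv[cur$sex == "F"],
                       scheme$selected_does_per_gen)
    sires <- select_top(cur$id[cur$sex == "M"], ebv[cur$sex == "M"],
                        scheme$selected_sires_per_gen)
    set.seed(derive_seed(seed, "litters", g))
    sizes <- .allocate_litters(scheme$cohort_females + scheme$cohort_males,
                               length(dams))
    cur_ids <- breed(g, dams, sires, sizes, seed)
    drop_gametes_before(g)
    g <- g + 1L
  }

  # ---- phase (c): genomic generations ------------------------------------
  for (k in seq_len(scheme$genomic_generations)) {
    pd <- do.call(rbind, ped)
    ctx <- list(generation = g - 1L, cohort_ids = cur_ids,
                get_dosage = get_dosage, map = map)
    ebv <- genomic_evaluator(pd, ctx)
    stopifnot(length(ebv) == length(cur_ids))
    cur <- pd[match(cur_ids, pd$id), ]
    dams <- cur$id[cur$sex == "F"]  # the full doe cohort serves as dams
    sires <- select_top(cur$id[cur$sex == "M"], ebv[cur$sex == "M"],
                        scheme$selected_sires_per_gen)
    n_kits <- if (k == scheme$genomic_generations) {
      scheme$final_females + scheme$final_males
    } else {
      scheme$cohort_females + scheme$cohort_males
    }
    sizes <- rep(n_kits %/% length(dams), length(dams))
    stopifnot(sum(sizes) == n_kits)  # scheme_config enforces divisibility
    cur_ids <- breed(g, dams, sires, sizes, seed)
    drop_gametes_before(g)
    g <- g + 1L
  }

  ped_df <- do.call(rbind, ped)
  ped_df$generation <- gen_label(ped_df$generation)
  names(gam) <- as.character(gen_label(as.integer(names(gam))))
  rownames(ped_df) <- NULL
  summ <- do.call(rbind, lapply(split(ped_df, ped_df$generation), function(d)
    data.frame(generation = d$generation[1], n = nrow(d),
               mean_tbv = mean(d$tbv), sd_tbv = stats::sd(d$tbv))))
  rownames(summ) <- NULL
  list(ped = ped_df, gametes = gam, map = map,
       generations = c(foundation = gen_label(0L), last = last_gen),
       summary = summ[order(summ$generation), ], scheme = scheme,
       get_dosage = get_dosage)
}
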