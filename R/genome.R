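#' Founder-genome configuration
#'
#' Describes the simulated rabbit genome and the forward Wright-Fisher burn-in
#' that generates founder haplotypes with linkage disequilibrium. Defaults
#' follow the full-scale study conditions: 20 chromosomes of 100 cM and
#' 124.43 Mb, 2000 founder haplotypes per chromosome, per-bp recombination
#' 8.57e-9 and mutation 1.74e-9. The burn-in tracks a fixed set of candidate
#' sites placed evenly on the physical map; each tracked site stands for the
#' surrounding window of sequence, so its per-generation mutation probability
#' is `mutation_rate_per_bp * chrom_length_bp / n_sites_per_chromosome`.
#' The effective-size schedule is a simple two-epoch approximation (large
#' ancestral, smaller recent population) followed by a terminal expansion
#' generation that samples `n_founder_haplotypes` haplotypes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM genetic length per chromosome (centimorgans).
#' @param chrom_length_bp physical length per chromosome (base pairs).
#' @param recomb_rate_per_bp per-site recombination rate (carried for
#'   reference; crossovers are placed on the linear bp-to-cM map).
#' @param mutation_rate_per_bp per-site mutation rate.
#' @param n_founder_haplotypes haplotypes sampled per chromosome (even).
#' @param n_sites_per_chromosome candidate sites tracked per chromosome.
#' @param effective_size_schedule data.frame with columns `generations` and
#'   `ne`: successive burn-in epochs (diploid effective sizes).
#' @param seed integer seed for the founder simulation.
#' @return an object of class `genome_config`.
#' @export
genome_config <- function(n_chromosomes = 20,
                          chrom_length_cM = 100,
                          chrom_length_bp = 124.43e6,
                          recomb_rate_per_bp = 8.57e-9,
                          mutation_rate_per_bp = 1.74e-9,
                          n_founder_haplotypes = 2000,
                          n_sites_per_chromosome = 5000,
                          effective_size_schedule =
                            data.frame(generations = c(1000, 100),
                                       ne = c(1000, 200)),
                          seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_cM = chrom_length_cM,
              chrom_length_bp = chrom_length_bp,
              recomb_rate_per_bp = recomb_rate_per_bp,
              mutation_rate_per_bp = mutation_rate_per_bp,
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              n_sites_per_chromosome = as.integer(n_sites_per_chromosome),
              effective_size_schedule = effective_size_schedule,
              seed = as.integer(seed))
  class(cfg) <- "genome_config"
  validate_genome_config(cfg)
  cfg
}

validate_genome_config <- function(cfg) {
  stopifnot(inherits(cfg, "genome_config"))
  pos <- c(n_chromosomes = cfg$n_chromosomes,
           chrom_length_cM = cfg$chrom_length_cM,
           chrom_length_bp = cfg$chrom_length_bp,
           n_founder_haplotypes = cfg$n_founder_haplotypes,
           n_sites_per_chromosome = cfg$n_sites_per_chromosome)
  if (any(pos <= 0)) {
    stop("genome_config: strictly positive values required for ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  if (cfg$recomb_rate_per_bp < 0 || cfg$mutation_rate_per_bp < 0) {
    stop("genome_config: rates must be non-negative")
  }
  if (cfg$n_founder_haplotypes %% 2L != 0L) {
    stop("genome_config: n_founder_haplotypes must be even ",
         "(haplotypes pair into diploids)")
  }
  es <- cfg$effective_size_schedule
  if (!is.data.frame(es) || !all(c("generations", "ne") %in% names(es)) ||
      any(es$generations <= 0) || any(es$ne <= 0)) {
    stop("genome_config: effective_size_schedule needs positive ",
         "'generations' and 'ne' columns")
  }
  invisible(cfg)
}

#' Simulate founder haplotypes by forward Wright-Fisher burn-in
#'
#' Runs a discrete-generation neutral Wright-Fisher simulation per chromosome:
#' the population starts monomorphic, mutation (symmetric 0/1 flips at the
#' tracked candidate sites) instantiates polymorphism, recombination follows
#' the linear bp-to-cM map (Poisson crossover counts, no interference), and
#' drift under the two-epoch effective-size schedule shapes allele frequencies
#' and linkage disequilibrium. Only segregating sites are retained.
#'
#' @param config a [genome_config()].
#' @param min_segregating_per_chromosome minimum segregating sites each
#'   chromosome must yield (e.g. HD panel share plus QTNs); an informative
#'   error is raised on shortfall.
#' @return an object of class `haplotype_pool`: per chromosome a raw 0/1
#'   haplotype matrix (haplotypes x segregating sites), bp and cM positions,
#'   and allele frequencies.
#' @export
simulate_founders <- function(config, min_segregating_per_chromosome = 0L) {
  validate_genome_config(config)
  ns <- config$n_sites_per_chromosome
  L <- config$chrom_length_bp
  mu_site <- config$mutation_rate_per_bp * L / ns
  es <- config$effective_size_schedule
  if (2L * es$ne[nrow(es)] > 1e7) stop("effective size schedule too large")
  pos_bp <- floor((seq_len(ns) - 0.5) * L / ns)
  pos_cM <- pos_bp * config$chrom_length_cM / L
  chroms <- vector("list", config$n_chromosomes)
  for (cc in seq_len(config$n_chromosomes)) {
    set.seed(derive_seed(config$seed, "founders", cc))
    H <- .wf_burnin_chr(ns, pos_cM, config$chrom_length_cM, mu_site,
                        as.integer(es$generations), as.integer(es$ne),
                        config$n_founder_haplotypes)
    cnt <- .col_counts(H)
    seg <- cnt > 0L & cnt < nrow(H)
    if (sum(seg) < min_segregating_per_chromosome) {
      stop(sprintf(paste0(
        "simulate_founders: chromosome %d yielded %d segregating sites but ",
        "%d are required; increase mutation_rate_per_bp, ",
        "n_sites_per_chromosome or the burn-in length"),
        cc, sum(seg), min_segregating_per_chromosome))
    }
    chroms[[cc]] <- list(haplotypes = H[, seg, drop = FALSE],
                         pos_bp = pos_bp[seg],
                         pos_cM = pos_cM[seg],
                         freq = cnt[seg] / nrow(H))
  }
  pool <- list(chromosomes = chroms, config = config)
  class(pool) <- "haplotype_pool"
  pool
}

# per-column allele-1 counts of a raw 0/1 matrix
.col_counts <- function(H) {
  colSums(matrix(as.integer(H), nrow(H), ncol(H)))
}

#' @exportS3Method base::print
#' @noRd
print.haplotype_pool <- function(x, ...) {
  ns <- vapply(x$chromosomes, function(ch) length(ch$pos_bp), integer(1))
  cat("haplotype_pool:", length(x$chromosomes), "chromosomes,",
      nrow(x$chromosomes[[1]]$haplotypes), "haplotypes,",
      sum(ns), "segregating sites\n")
  invisible(x)
}

#' Flatten a haplotype pool into one genome-wide site coordinate system
#'
#' Concatenates chromosomes into a single haplotype matrix with global site
#' indices (chromosomes in order, positions ascending). All downstream
#' bookkeeping (QTNs, marker panels, gene drop, imputation) uses these global
#' column indices.
#'
#' @param pool a `haplotype_pool`.
#' @return list with `hap` (raw matrix haplotypes x total sites), `site_chr`,
#'   `site_bp`, `site_cM`, `freq`, `chr_start` (1-based global index of each
#'   chromosome's first site) and `chr_len_cM`.
#' @export
flatten_pool <- function(pool) {
  stopifnot(inherits(pool, "haplotype_pool"))
  ns <- vapply(pool$chromosomes, function(ch) length(ch$pos_bp), integer(1))
  hap <- do.call(cbind, lapply(pool$chromosomes, `[[`, "haplotypes"))
  list(hap = hap,
       site_chr = rep(seq_along(ns), ns),
       site_bp = unlist(lapply(pool$chromosomes, `[[`, "pos_bp")),
       site_cM = unlist(lapply(pool$chromosomes, `[[`, "pos_cM")),
       freq = unlist(lapply(pool$chromosomes, `[[`, "freq")),
       chr_start = cumsum(c(1L, ns[-length(ns)])),
       chr_len_cM = rep(pool$config$chrom_length_cM, length(ns)))
}

# genetic map of a flattened pool restricted to columns `keep` (sorted)
.map_restrict <- function(flat, keep) {
  keep <- sort(unique(as.integer(keep)))
  chr <- flat$site_chr[keep]
  list(site_chr = chr,
       site_bp = flat$site_bp[keep],
       site_cM = flat$site_cM[keep],
       freq = flat$freq[keep],
       chr_start = match(unique(chr), chr),
       chr_len_cM = flat$chr_len_cM[unique(chr)],
       orig_idx = keep)
}

#' Pair founder haplotypes into diploid individuals
#'
#' Randomly assigns pool haplotypes to diploid founders, each haplotype used
#' at most once.
#'
#' @param pool a `haplotype_pool` (or flattened pool).
#' @param n_individuals number of diploids to draw.
#' @param seed integer seed.
#' @return integer matrix `n_individuals` x 2 of haplotype row indices.
#' @export
draw_diploid_founders <- function(pool, n_individuals, seed = NULL) {
  n_hap <- if (inherits(pool, "haplotype_pool")) {
    nrow(pool$chromosomes[[1]]$haplotypes)
  } else {
    nrow(pool$hap)
  }
  n_individuals <- as.integer(n_individuals)
  if (2L * n_individuals > n_hap) {
    stop(sprintf(paste0("draw_diploid_founders: %d diploids need %d ",
                        "haplotypes but the pool holds %d"),
                 n_individuals, 2L * n_individuals, n_hap))
  }
  if (n_individuals == 0L) {
    return(matrix(integer(0), 0L, 2L))
  }
  .seed_if(seed)
  idx <- sample.int(n_hap, 2L * n_individuals)
  matrix(idx, ncol = 2L, byrow = TRUE)
}

#' Export founder haplotypes as a phased VCF
#'
#' Writes one VCFv4.2 record per segregating site with phased `GT` fields,
#' one contig per chromosome; haplotypes `2i-1` and `2i` form sample `i`.
#'
#' @param pool a `haplotype_pool`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_founders_vcf <- function(pool, path) {
  stopifnot(inherits(pool, "haplotype_pool"))
  n_hap <- nrow(pool$chromosomes[[1]]$haplotypes)
  n_ind <- n_hap %/% 2L
  samples <- sprintf("F%04d", seq_len(n_ind))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chr%d,length=%d>",
                       seq_along(pool$chromosomes),
                       as.integer(pool$config$chrom_length_bp)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (cc in seq_along(pool$chromosomes)) {
    ch <- pool$chromosomes[[cc]]
    H <- matrix(as.integer(ch$haplotypes), nrow = n_hap)
    for (j in seq_along(ch$pos_bp)) {
      gt <- paste(H[seq(1, n_hap, 2), j], H[seq(2, n_hap, 2), j], sep = "|")
      writeLines(paste(c(sprintf("chr%d", cc), ch$pos_bp[j] + 1L,
                         sprintf("chr%d_%d", cc, j), "A", "B", ".", "PASS",
                         ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}
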