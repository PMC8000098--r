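test_that("configuration defaults mirror the full-scale study genome", {
  gc <- genome_config()
  expect_equal(gc$n_chromosomes, 20L)
  expect_equal(gc$n_founder_haplotypes, 2000L)
  expect_equal(gc$chrom_length_cM, 100)
  expect_equal(gc$chrom_length_bp, 124.43e6)
  expect_equal(gc$recomb_rate_per_bp, 8.57e-9)
  expect_equal(gc$mutation_rate_per_bp, 1.74e-9)
})

test_that("configuration invariants are enforced", {
  expect_error(genome_config(n_founder_haplotypes = 601), "even")
  expect_error(genome_config(n_chromosomes = 0), "positive")
  expect_error(genome_config(mutation_rate_per_bp = -1), "non-negative")
})

test_that("no mutation on a monomorphic start yields the shortfall error", {
  gc <- genome_config(n_chromosomes = 1, n_founder_haplotypes = 40,
                      n_sites_per_chromosome = 200,
                      mutation_rate_per_bp = 0,
                      effective_size_schedule =
                        data.frame(generations = 10, ne = 20), seed = 1)
  expect_error(simulate_founders(gc, min_segregating_per_chromosome = 1L),
               "0 segregating sites")
})

test_that("pool sites are segregating, ordered, and on the linear cM map", {
  pool <- tiny_pool()
  for (ch in pool$chromosomes) {
    expect_true(all(ch$freq > 0 & ch$freq < 1))
    expect_true(all(diff(ch$pos_bp) > 0))
    expect_true(all(ch$pos_bp >= 0 &
                      ch$pos_bp < pool$config$chrom_length_bp))
    expect_equal(ch$pos_cM, ch$pos_bp * pool$config$chrom_length_cM /
                   pool$config$chrom_length_bp)
    expect_true(all(as.integer(ch$haplotypes) %in% 0:1))
  }
})

test_that("identical seed and config reproduce the pool bit for bit", {
  gc <- genome_config(n_chromosomes = 1, n_founder_haplotypes = 60,
                      n_sites_per_chromosome = 400,
                      mutation_rate_per_bp = 1e-8,
                      effective_size_schedule =
                        data.frame(generations = 30, ne = 30), seed = 5)
  p1 <- simulate_founders(gc)
  p2 <- simulate_founders(gc)
  expect_identical(p1$chromosomes[[1]]$haplotypes,
                   p2$chromosomes[[1]]$haplotypes)
  expect_identical(p1$chromosomes[[1]]$pos_bp, p2$chromosomes[[1]]$pos_bp)
})

test_that("mean heterozygosity matches an independent single-locus WF run", {
  epochs <- data.frame(generations = 200, ne = 100)
  n_chr <- 8L
  sites_per_chr <- 250L
  mu_bp <- 1e-8
  gc <- genome_config(n_chromosomes = n_chr, n_founder_haplotypes = 200,
                      n_sites_per_chromosome = sites_per_chr,
                      mutation_rate_per_bp = mu_bp,
                      effective_size_schedule = epochs, seed = 31)
  pool <- simulate_founders(gc)
  # mean 2p(1-p) over all tracked sites (monomorphic sites contribute 0)
  het_chr <- vapply(pool$chromosomes, function(ch)
    sum(2 * ch$freq * (1 - ch$freq)) / sites_per_chr, numeric(1))
  u <- mu_bp * gc$chrom_length_bp / sites_per_chr
  pf <- wf_oracle_freqs(10000L, epochs, u, 200L, seed = 77)
  het_oracle <- 2 * pf * (1 - pf)
  tol <- 3 * sqrt(stats::var(het_chr) / n_chr +
                    stats::var(het_oracle) / length(het_oracle))
  expect_lt(abs(mean(het_chr) - mean(het_oracle)), tol)
})

test_that("linkage disequilibrium decays with genetic distance", {
  pool <- tiny_pool()
  fl <- flatten_pool(pool)
  set.seed(8)
  r2_sum <- c(0, 0, 0)
  r2_n <- c(0, 0, 0)
  for (cc in 1:3) {
    idx <- which(fl$site_chr == cc)
    s <- sort(sample(idx, 120))
    H <- matrix(as.integer(fl$hap[, s]), nrow = nrow(fl$hap))
    cm <- fl$site_cM[s]
    C <- suppressWarnings(stats::cor(H))
    D <- abs(outer(cm, cm, "-"))
    for (b in 1:3) {
      lims <- rbind(c(0, 1), c(1, 5), c(5, 20))[b, ]
      sel <- D >= lims[1] & D < lims[2] & upper.tri(D) & !is.na(C)
      r2_sum[b] <- r2_sum[b] + sum(C[sel]^2)
      r2_n[b] <- r2_n[b] + sum(sel)
    }
  }
  r2 <- r2_sum / r2_n
  expect_true(all(diff(r2) < 0))
})

test_that("diploid founder draws use each haplotype at most once", {
  pool <- tiny_pool()
  n_hap <- nrow(pool$chromosomes[[1]]$haplotypes)
  pairs <- draw_diploid_founders(pool, n_hap / 2, seed = 1)
  expect_equal(sort(as.vector(pairs)), seq_len(n_hap))
  expect_equal(nrow(draw_diploid_founders(pool, 0)), 0L)
  expect_error(draw_diploid_founders(pool, n_hap / 2 + 1),
               "haplotypes")
})

test_that("founder VCF export writes phased genotypes for every site", {
  gc <- genome_config(n_chromosomes = 2, n_founder_haplotypes = 20,
                      n_sites_per_chromosome = 150,
                      mutation_rate_per_bp = 2e-8,
                      effective_size_schedule =
                        data.frame(generations = 20, ne = 15), seed = 3)
  pool <- simulate_founders(gc)
  path <- tempfile(fileext = ".vcf")
  write_founders_vcf(pool, path)
  lines <- readLines(path)
  n_sites <- sum(vapply(pool$chromosomes, function(ch) length(ch$pos_bp),
                        integer(1)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), n_sites)
  gt <- strsplit(body[1], "\t")[[1]][-(1:9)]
  expect_equal(length(gt), 10L)
  expect_true(all(grepl("^[01]\\|[01]$", gt)))
})
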