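test_that("a homozygous parent phases the offspring's heterozygous marker", {
  # 10-marker chromosome: sire homozygous 0 everywhere, dam phased 1|0
  S <- 10
  map <- toy_map(S)
  sire <- list(h1 = rep(0, S), h2 = rep(0, S))
  dam <- list(h1 = rep(1, S), h2 = rep(0, S))
  out <- impute_individual(1:S, rep(1, S), sire, dam, map)
  expect_equal(out$pat, rep(0, S))
  expect_equal(out$mat, rep(1, S))
  expect_equal(out$dosage, rep(1, S))
})

test_that("fully phased parents without recombination impute exactly", {
  # both parents homozygous at every marker: the offspring dosage is forced
  S <- 40
  map <- toy_map(S)
  set.seed(3)
  sa <- rbinom(S, 1, 0.5)
  da <- rbinom(S, 1, 0.5)
  sire <- list(h1 = sa, h2 = sa)
  dam <- list(h1 = da, h2 = da)
  typed <- seq(1, S, by = 8)
  out <- impute_individual(typed, (sa + da)[typed], sire, dam, map)
  expect_equal(out$dosage, sa + da)
})

test_that("unphased parents fall back to the frequency fill", {
  S <- 30
  map <- toy_map(S)
  set.seed(4)
  freq <- runif(S, 0.1, 0.9)
  fb <- list(h1 = freq, h2 = freq)
  typed <- c(5L, 20L)
  out <- impute_individual(typed, c(1, 1), fb, fb, map)
  untyped <- setdiff(1:S, typed)
  expect_equal(out$dosage[untyped], 2 * freq[untyped])
  expect_equal(out$dosage[typed], c(1, 1))
})

test_that("imputed hard calls agree with the gene-drop truth in a deep pedigree", {
  w <- tiny_world()
  masked <- apply_scenario("S1", w$sim$ped, w$panel, w$sim$get_dosage)
  map_hd <- list(site_cM = w$flat$site_cM[w$panel$hd],
                 chr_start = match(unique(w$flat$site_chr[w$panel$hd]),
                                   w$flat$site_chr[w$panel$hd]),
                 chr_len_cM = w$flat$chr_len_cM)
  imp <- run_imputation("S1", masked, w$sim$ped, map_hd,
                        freq = w$flat$freq[w$panel$hd])
  ids <- as.integer(rownames(imp$dosage))
  truth <- w$sim$get_dosage(ids, w$panel$hd)
  called <- !is.na(imp$hard)
  concord <- mean(imp$hard[called] == truth[called])
  expect_gte(concord, 0.95)
})

test_that("the pedigree imputer dominates a frequency-only imputer", {
  w <- tiny_world()
  masked <- apply_scenario("S2", w$sim$ped, w$panel, w$sim$get_dosage)
  map_hd <- list(site_cM = w$flat$site_cM[w$panel$hd],
                 chr_start = match(unique(w$flat$site_chr[w$panel$hd]),
                                   w$flat$site_chr[w$panel$hd]),
                 chr_len_cM = w$flat$chr_len_cM)
  freq <- w$flat$freq[w$panel$hd]
  imp <- run_imputation("S2", masked, w$sim$ped, map_hd, freq = freq)
  ids <- as.integer(rownames(imp$dosage))
  truth <- w$sim$get_dosage(ids, w$panel$hd)
  ia_ped <- imputation_accuracy(truth, imp$dosage, imp$untyped_cols)
  freq_fill <- matrix(2 * freq, nrow(truth), ncol(truth), byrow = TRUE)
  ia_frq <- imputation_accuracy(truth, freq_fill, imp$untyped_cols)
  expect_gte(ia_ped$mean, ia_frq$mean)
})

test_that("imputation is deterministic given identical inputs", {
  w <- tiny_world()
  masked <- apply_scenario("S4", w$sim$ped, w$panel, w$sim$get_dosage)
  map_hd <- list(site_cM = w$flat$site_cM[w$panel$hd],
                 chr_start = match(unique(w$flat$site_chr[w$panel$hd]),
                                   w$flat$site_chr[w$panel$hd]),
                 chr_len_cM = w$flat$chr_len_cM)
  i1 <- run_imputation("S4", masked, w$sim$ped, map_hd,
                       freq = w$flat$freq[w$panel$hd])
  i2 <- run_imputation("S4", masked, w$sim$ped, map_hd,
                       freq = w$flat$freq[w$panel$hd])
  expect_identical(i1$dosage, i2$dosage)
  expect_identical(i1$hard, i2$hard)
})

test_that("whole-genome imputation is the parent average with sparse calls", {
  phased <- new.env(parent = emptyenv())
  assign("1", list(dosage = c(2, 1, 0, 2)), envir = phased)
  assign("2", list(dosage = c(2, 1, 2, 0)), envir = phased)
  d <- impute_whole_genome(1L, 2L, phased, freq = rep(0.5, 4))
  expect_equal(d, c(2, 1, 1, 1))
  expect_error(impute_whole_genome(1L, 0L, phased, rep(0.5, 4)),
               "both parents")
  # hard-call rule: both parents homozygous
  hc <- hard_calls(matrix(d, 1))
  expect_equal(as.vector(hc), c(2L, 1L, 1L, 1L))
})

test_that("non-genotyped full sibs receive identical whole genomes", {
  w <- tiny_world()
  masked <- apply_scenario("S3_A", w$sim$ped, w$panel, w$sim$get_dosage,
                           seed = 31)
  map_hd <- list(site_cM = w$flat$site_cM[w$panel$hd],
                 chr_start = match(unique(w$flat$site_chr[w$panel$hd]),
                                   w$flat$site_chr[w$panel$hd]),
                 chr_len_cM = w$flat$chr_len_cM)
  imp <- run_imputation("S3_A", masked, w$sim$ped, map_hd,
                        freq = w$flat$freq[w$panel$hd])
  wg <- imp$candidates[imp$candidates$platform == "WG", ]
  expect_gt(nrow(wg), 0)
  ped <- w$sim$ped
  fam <- paste(ped$sire[match(wg$id, ped$id)],
               ped$dam[match(wg$id, ped$id)])
  dup <- split(wg$id, fam)
  dup <- dup[lengths(dup) >= 2][[1]]
  r1 <- imp$dosage[as.character(dup[1]), ]
  r2 <- imp$dosage[as.character(dup[2]), ]
  expect_identical(r1, r2)
  # typed half is still imputed normally
  expect_equal(sort(unique(imp$candidates$platform)), c("LD", "WG"))
  # each whole-genome row duplicates a genotyped full sib's imputed genome
  fam_of <- function(ids) paste(ped$sire[match(ids, ped$id)],
                                ped$dam[match(ids, ped$id)])
  kept <- imp$candidates[imp$candidates$imputed, ]
  ld_ids <- kept$id[kept$platform == "LD"]
  for (id in wg$id[1:3]) {
    sib_rows <- as.character(ld_ids[fam_of(ld_ids) == fam_of(id)])
    expect_true(any(vapply(sib_rows, function(sr)
      identical(imp$dosage[as.character(id), ], imp$dosage[sr, ]),
      logical(1))))
  }
})

test_that("accuracy bookkeeping follows its definition", {
  set.seed(6)
  true <- matrix(sample(0:2, 300, replace = TRUE), 3, 100)
  # perfect imputation
  ia <- imputation_accuracy(true, true + 0.0, untyped_cols = 1:100)
  expect_equal(ia$per_individual$r, rep(1, 3))
  # constant vector: undefined, excluded
  const <- matrix(1.0, 3, 100)
  ia2 <- imputation_accuracy(true, const, untyped_cols = 1:100)
  expect_equal(ia2$n_excluded, 3L)
  expect_true(all(is.na(ia2$per_individual$r)))
  # independent noise: correlation near zero
  big <- matrix(sample(0:2, 10000, replace = TRUE), 1, 10000)
  noise <- matrix(runif(10000, 0, 2), 1, 10000)
  ia3 <- imputation_accuracy(big, noise, untyped_cols = 1:10000)
  expect_lt(abs(ia3$mean), 0.03)
  expect_error(imputation_accuracy(true, true + 0.0,
                                   untyped_cols = integer(0)), "empty")
})

test_that("genotype yield counts hard calls at untyped markers", {
  h <- matrix(c(0L, 1L, NA, 2L, NA, NA), 2, 3, byrow = TRUE)
  y <- genotype_yield(h, untyped_cols = 1:3)
  expect_equal(y$per_individual$yield, c(2 / 3, 1 / 3))
  expect_equal(genotype_yield(matrix(1L, 2, 4), 1:4)$mean, 1)
  expect_equal(genotype_yield(matrix(NA_integer_, 2, 4), 1:4)$mean, 0)
})

test_that("typed markers pass through unchanged (mask discipline)", {
  w <- tiny_world()
  masked <- apply_scenario("S1", w$sim$ped, w$panel, w$sim$get_dosage)
  map_hd <- list(site_cM = w$flat$site_cM[w$panel$hd],
                 chr_start = match(unique(w$flat$site_chr[w$panel$hd]),
                                   w$flat$site_chr[w$panel$hd]),
                 chr_len_cM = w$flat$chr_len_cM)
  imp <- run_imputation("S1", masked, w$sim$ped, map_hd,
                        freq = w$flat$freq[w$panel$hd])
  ids <- rownames(imp$dosage)
  md_cols <- match(w$panel$md, w$panel$hd)
  truth <- w$sim$get_dosage(as.integer(ids), w$panel$md)
  expect_equal(unname(imp$dosage[, md_cols]), unname(truth + 0.0))
  # untyped sets exclude typed markers
  for (k in seq_along(imp$untyped_cols)[1:3]) {
    expect_length(intersect(imp$untyped_cols[[k]], imp$typed_cols[[k]]), 0)
  }
})

test_that("a conflicting declared parent is ignored with a warning", {
  S <- 60
  map <- toy_map(S)
  freq <- rep(0.5, S)
  ped <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                    sex = c("M", "F", "F"), generation = c(26L, 26L, 28L))
  geno <- rbind(rep(2L, S), rep(0L, S), rep(0L, S))  # offspring vs sire: all
  rownames(geno) <- 1:3                              # opposing homozygotes
  roles <- data.frame(id = 1:3,
                      role = c("sires", "dams", "progeny"),
                      platform = c("HD", "HD", "MD"))
  masked <- list(geno = geno, roles = roles, hd_idx = seq_len(S))
  expect_warning(
    run_imputation("S1", masked, ped, map, freq),
    "Mendelian conflict")
})
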