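test_that("a zero-length map passes one parental haplotype through", {
  map <- list(site_cM = rep(0, 50), chr_start = 1L, chr_len_cM = 0)
  h1 <- as.raw(rep(0, 50)); h2 <- as.raw(rep(1, 50))
  g <- meiosis(h1, h2, map, seed = 1)
  expect_true(identical(g, h1) || identical(g, h2))
})

test_that("crossover count matches the Poisson map length", {
  # parent haplotypes all-0 / all-1: observable switches count crossovers
  n <- 2000
  map <- toy_map(n)
  h1 <- as.raw(rep(0, n)); h2 <- as.raw(rep(1, n))
  set.seed(21)
  xo <- replicate(10000, {
    g <- as.integer(meiosis(h1, h2, map))
    sum(diff(g) != 0)
  })
  expect_lt(abs(mean(xo) - 1.0), 0.03)
})

test_that("recombinant fraction at 50 cM matches the Haldane map function", {
  map <- list(site_cM = c(25, 75), chr_start = 1L, chr_len_cM = 100)
  h1 <- as.raw(c(0, 0)); h2 <- as.raw(c(1, 1))
  set.seed(22)
  rec <- replicate(10000, {
    g <- as.integer(meiosis(h1, h2, map))
    g[1] != g[2]
  })
  haldane <- (1 - exp(-1)) / 2
  se <- sqrt(haldane * (1 - haldane) / 10000)
  expect_lt(abs(mean(rec) - haldane), 3 * se)
})

test_that("litters split sexes 1:1 and alleles are Mendelian", {
  w <- tiny_world()
  g27 <- w$sim$gametes[["27"]]
  pick <- function(k) list(pat = g27$pat[k, ], mat = g27$mat[k, ],
                           sex = w$sim$ped$sex[match(g27$ids[k],
                                                     w$sim$ped$id)])
  dam <- pick(which(w$sim$ped$sex[match(g27$ids, w$sim$ped$id)] == "F")[1])
  sire <- pick(which(w$sim$ped$sex[match(g27$ids, w$sim$ped$id)] == "M")[1])
  off <- mate(dam, sire, 20, w$sim$map, w$arch, seed = 5)
  expect_equal(sum(vapply(off, `[[`, character(1), "sex") == "F"), 10L)
  for (o in off[1:5]) {
    po <- as.integer(o$pat); mo <- as.integer(o$mat)
    expect_true(all(po == as.integer(sire$pat) | po ==
                      as.integer(sire$mat)))
    expect_true(all(mo == as.integer(dam$pat) | mo == as.integer(dam$mat)))
  }
  expect_error(mate(dam, dam, 2, w$sim$map, w$arch), "same-sex")
})

test_that("offspring TBV centres on the mid-parent value", {
  w <- tiny_world()
  g27 <- w$sim$gametes[["27"]]
  sex <- w$sim$ped$sex[match(g27$ids, w$sim$ped$id)]
  dam_k <- which(sex == "F")[2]; sire_k <- which(sex == "M")[2]
  dam <- list(pat = g27$pat[dam_k, ], mat = g27$mat[dam_k, ], sex = "F")
  sire <- list(pat = g27$pat[sire_k, ], mat = g27$mat[sire_k, ], sex = "M")
  off <- mate(dam, sire, 1000, w$sim$map, w$arch, seed = 6)
  tbv_off <- vapply(off, `[[`, numeric(1), "tbv")
  midparent <- mean(true_breeding_value(rbind(
    as.integer(dam$pat[w$arch$qtn_idx]) +
      as.integer(dam$mat[w$arch$qtn_idx]),
    as.integer(sire$pat[w$arch$qtn_idx]) +
      as.integer(sire$mat[w$arch$qtn_idx])), w$arch))
  se <- stats::sd(tbv_off) / sqrt(length(tbv_off))
  expect_lt(abs(mean(tbv_off) - midparent), 3 * se)
})

test_that("the program produces the scheme's cohort sizes in order", {
  w <- tiny_world()
  ped <- w$sim$ped
  tab <- table(ped$generation, ped$sex)
  gens <- sort(unique(ped$generation))
  g_last <- max(gens)
  for (g in setdiff(gens, g_last)) {
    expect_equal(unname(tab[as.character(g), ]), c(20L, 20L))
  }
  expect_equal(unname(tab[as.character(g_last), ]), c(100L, 100L))
  # topological order: parents precede offspring
  pos <- match(ped$id, ped$id)
  known <- ped$sire > 0
  expect_true(all(match(ped$sire[known], ped$id) < pos[known]))
  known <- ped$dam > 0
  expect_true(all(match(ped$dam[known], ped$id) < pos[known]))
  # parents born in strictly earlier generations
  expect_true(all(ped$generation[match(ped$sire[ped$sire > 0], ped$id)] <
                    ped$generation[ped$sire > 0]))
})

test_that("every non-founder allele descends from a parental allele", {
  w <- tiny_world()
  gam <- w$sim$gametes
  ped <- w$sim$ped
  gens <- sort(as.integer(names(gam)))
  for (g in gens[-1]) {
    cur <- gam[[as.character(g)]]
    prev <- gam[[as.character(g - 1L)]]
    rows <- match(cur$ids, ped$id)
    for (k in sample(seq_along(cur$ids), 5)) {
      sire_k <- match(ped$sire[rows[k]], prev$ids)
      dam_k <- match(ped$dam[rows[k]], prev$ids)
      po <- as.integer(cur$pat[k, ])
      expect_true(all(po == as.integer(prev$pat[sire_k, ]) |
                        po == as.integer(prev$mat[sire_k, ])))
      mo <- as.integer(cur$mat[k, ])
      expect_true(all(mo == as.integer(prev$pat[dam_k, ]) |
                        mo == as.integer(prev$mat[dam_k, ])))
    }
  }
})

test_that("selected parents are exactly the callback's top-k", {
  w <- tiny_world()
  # rerun with a deterministic callback: EBV = TBV (oracle selection)
  oracle <- function(ped, ctx) ped$tbv[match(ctx$cohort_ids, ped$id)]
  sim <- run_program(w$flat, w$arch, w$scheme, evaluator = oracle,
                     seed = 13)
  ped <- sim$ped
  gens <- sort(unique(ped$generation))
  # check one BLUP-phase selection: parents of generation g+1
  g <- gens[5]
  cohort <- ped[ped$generation == g, ]
  nxt <- ped[ped$generation == g + 1L, ]
  top_d <- cohort$id[cohort$sex == "F"]
  top_d <- top_d[order(-cohort$tbv[cohort$sex == "F"], top_d)][1:8]
  top_s <- cohort$id[cohort$sex == "M"]
  top_s <- top_s[order(-cohort$tbv[cohort$sex == "M"], top_s)][1:4]
  expect_setequal(unique(nxt$dam), top_d)
  expect_setequal(unique(nxt$sire), top_s)
})

test_that("oracle selection beats random selection on genetic gain", {
  w <- tiny_world()
  oracle <- function(ped, ctx) ped$tbv[match(ctx$cohort_ids, ped$id)]
  gain <- function(evaluator, seed) {
    sim <- run_program(w$flat, w$arch, w$scheme, evaluator = evaluator,
                       seed = seed)
    s <- sim$summary
    s$mean_tbv[nrow(s)] - s$mean_tbv[1]
  }
  noise <- function(ped, ctx) stats::rnorm(length(ctx$cohort_ids))
  gains_oracle <- gains_noise <- numeric(4)
  for (r in 1:4) {
    gains_oracle[r] <- gain(oracle, seed = 100 + r)
    gains_noise[r] <- gain(noise, seed = 100 + r)
  }
  expect_gt(mean(gains_oracle), mean(gains_noise))
  # response to selection is positive in every replicate
  expect_true(all(gains_oracle > 0))
})
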