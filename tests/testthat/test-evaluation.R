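trio_ped <- function() {
  data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
             sex = c("M", "F", "F"), generation = c(0L, 0L, 1L))
}

test_that("inbreeding coefficients match textbook cases", {
  expect_equal(inbreeding(trio_ped()), c(0, 0, 0))
  # offspring of full sibs from unrelated grandparents: F = 0.25
  ped <- data.frame(id = 1:5,
                    sire = c(0L, 0L, 1L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 4L),
                    generation = c(0L, 0L, 1L, 1L, 2L))
  expect_equal(inbreeding(ped)[5], 0.25)
})

test_that("tabular A and F match the recursive kinship oracle", {
  ped <- random_pedigree(8, 32, seed = 14)
  A <- tabular_a(ped)
  A_oracle <- kinship_oracle(ped)
  expect_equal(A, A_oracle, tolerance = 1e-12)
  expect_equal(inbreeding(ped), unname(diag(A_oracle)) - 1,
               tolerance = 1e-12)
  bad <- ped[rev(seq_len(nrow(ped))), ]
  expect_error(tabular_a(bad), "topologically")
})

test_that("Henderson's rules give the exact sparse inverse", {
  single <- data.frame(id = 1L, sire = 0L, dam = 0L)
  expect_equal(as.matrix(a_inverse(single)), matrix(1, 1, 1),
               ignore_attr = TRUE)
  # sire-dam-offspring trio with unrelated founders
  Ai <- as.matrix(a_inverse(trio_ped()))
  expect_equal(unname(Ai),
               rbind(c(1.5, 0.5, -1), c(0.5, 1.5, -1), c(-1, -1, 2)))
  # random pedigree with inbreeding: A^-1 A = I
  ped <- random_pedigree(6, 34, seed = 15)
  A <- tabular_a(ped)
  Ai <- as.matrix(a_inverse(ped))
  expect_equal(unname(Ai %*% A), diag(nrow(ped)), tolerance = 1e-8)
})

test_that("VanRaden G matches a brute-force double loop", {
  set.seed(16)
  dos <- matrix(sample(0:2, 100, replace = TRUE), 5, 20)
  p <- colMeans(dos) / 2
  G <- g_matrix(dos)
  manual <- matrix(0, 5, 5)
  denom <- 2 * sum(p * (1 - p))
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (k in 1:20) acc <- acc + (dos[i, k] - 2 * p[k]) *
        (dos[j, k] - 2 * p[k])
    manual[i, j] <- acc / denom
  }
  expect_equal(G, manual, tolerance = 1e-12)
  # duplicated genotype rows give identical self- and cross-relationships
  dup <- rbind(dos, dos[1, ])
  G2 <- g_matrix(dup)
  expect_equal(G2[1, 1], G2[6, 6])
  expect_equal(G2[1, 6], G2[1, 1])
  # homozygous carrier of rare alleles has an inflated self-relationship
  rare <- rbind(matrix(0L, 9, 10), rep(2L, 10))
  Gr <- g_matrix(rare)
  expect_gt(Gr[10, 10], 1)
  expect_error(g_matrix(matrix(0L, 3, 4)), "segregating")
})

test_that("blending mixes G with A22 at the stated weight", {
  set.seed(17)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  a22 <- diag(6)
  G0 <- g_matrix(dos)
  Gb <- g_matrix(dos, a22 = a22, blend = 0.05)
  expect_equal(Gb, 0.95 * G0 + 0.05 * a22, tolerance = 1e-12)
})

test_that("QC removes exactly the failing markers and animals", {
  # 10 markers: 3 with MAF < 0.05, one animal at 85% call rate
  set.seed(18)
  n <- 40
  hard <- cbind(matrix(rbinom(n * 7, 2, 0.5), n, 7),
                matrix(rbinom(n * 3, 2, 0.01), n, 3))
  hard[1, sample(7, 2)] <- NA  # animal 1: 5/7 = 71% on retained markers
  qc <- qc_genotypes(hard)
  expect_equal(sum(!qc$keep_sites), 3L)
  expect_equal(which(!qc$keep_sites), 8:10)
  expect_equal(which(!qc$keep_animals), 1L)
  expect_equal(qc$report$sites_removed, 3L)
  expect_equal(qc$report$animals_removed, 1L)
  # complete high-MAF matrix passes untouched
  clean <- matrix(rbinom(200, 2, 0.5), 20, 10)
  qc2 <- qc_genotypes(clean)
  expect_true(all(qc2$keep_sites) && all(qc2$keep_animals))
  expect_error(qc_genotypes(matrix(c(0L, 0L, 0L, 0L), 2, 2)), "filtered")
})

test_that("H-inverse reduces to A-inverse in the degenerate cases", {
  ped <- random_pedigree(6, 14, seed = 19)
  Ai <- a_inverse(ped)
  expect_identical(h_inverse(Ai, matrix(0, 0, 0), matrix(0, 0, 0),
                             integer(0)), Ai)
  A <- tabular_a(ped)
  idx <- c(3L, 9L, 17L)
  A22 <- A[idx, idx]
  H1 <- h_inverse(Ai, A22, A22, idx)
  expect_equal(as.matrix(H1), as.matrix(Ai), tolerance = 1e-10)
})

test_that("solving with H-inverse equals the dense partitioned-H oracle", {
  ped <- random_pedigree(4, 4, seed = 20)  # 8 animals, 3 genotyped
  A <- tabular_a(ped)
  idx <- c(4L, 6L, 8L)
  set.seed(21)
  dos <- matrix(sample(0:2, 3 * 30, replace = TRUE), 3, 30)
  A22 <- A[idx, idx]
  G <- g_matrix(dos, a22 = A22, blend = 0.05)
  Hi <- h_inverse(a_inverse(ped), G, A22, idx)
  # dense oracle: assemble H itself by the partitioned-matrix identity and
  # solve the MME with K = H directly
  A11 <- A[-idx, -idx]; A12 <- A[-idx, idx]
  A22i <- solve(A22)
  H <- matrix(0, 8, 8)
  H[-idx, -idx] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H[-idx, idx] <- A12 %*% A22i %*% G
  H[idx, -idx] <- t(H[-idx, idx])
  H[idx, idx] <- G
  y <- c(9.8, 10.4, 11.1, 9.5)
  rec <- c(2L, 4L, 6L, 7L)
  lambda <- 2.5
  sol <- solve_mme(y, rec, Hi, lambda, "ssGBLUP")
  oracle <- dense_mme_oracle(y, rec, H, lambda)
  expect_equal(unname(sol$ebv), unname(oracle$ebv), tolerance = 1e-6)
  expect_equal(sol$mu, oracle$mu, tolerance = 1e-6)
  expect_error(h_inverse(a_inverse(ped), matrix(0, 3, 3), A22, idx),
               "singular")
})

test_that("MME solutions match dense inversion and shrink correctly", {
  ped <- random_pedigree(3, 3, seed = 22)  # 6 animals
  A <- tabular_a(ped)
  Ai <- a_inverse(ped)
  y <- c(10.2, 9.1, 11.3)
  rec <- c(1L, 3L, 5L)
  sol <- solve_mme(y, rec, Ai, lambda = 3, "BLUP")
  oracle <- dense_mme_oracle(y, rec, A, lambda = 3)
  expect_equal(unname(sol$ebv), unname(oracle$ebv), tolerance = 1e-8)
  # unphenotyped relatives receive information through the pedigree
  unrec <- setdiff(which(ped$sire > 0 | ped$dam > 0), rec)
  expect_true(all(abs(sol$ebv[unrec]) > 0))
  # infinite shrinkage: EBVs collapse to zero, mu to the record mean
  sol_inf <- solve_mme(y, rec, Ai, lambda = 1e8, "BLUP")
  expect_lt(max(abs(sol_inf$ebv)), 1e-5)
  expect_equal(sol_inf$mu, mean(y), tolerance = 1e-5)
})

test_that("ssGBLUP collapses to BLUP with zero genotyped animals", {
  ped <- random_pedigree(6, 24, seed = 23)
  Ai <- a_inverse(ped)
  Hi <- h_inverse(Ai, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  set.seed(24)
  rec <- sample(nrow(ped), 12)
  y <- rnorm(12, 10)
  sb <- solve_mme(y, rec, Ai, lambda = 7.85, "BLUP")
  sh <- solve_mme(y, rec, Hi, lambda = 7.85, "ssGBLUP")
  expect_identical(sb$ebv, sh$ebv)
})

test_that("parent-average EBVs average the parents", {
  ped <- trio_ped()
  ebv <- c("1" = 0.4, "2" = 0.2, "3" = 0)
  expect_equal(parent_average_ebv(ped, ebv, 3L), 0.3)
  ebv0 <- c("1" = 0, "2" = 0, "3" = 1)
  expect_equal(parent_average_ebv(ped, ebv0, 3L), 0)
  expect_error(parent_average_ebv(ped, ebv, 1L), "unknown parent")
  # full sibs share the parent average
  ped2 <- rbind(ped, data.frame(id = 4L, sire = 1L, dam = 2L, sex = "F",
                                generation = 1L))
  ebv2 <- c(ebv, "4" = 9)
  expect_equal(parent_average_ebv(ped2, ebv2, c(3L, 4L)), c(0.3, 0.3))
})
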