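# Independent oracles used to freeze expected values. Each one deliberately
# takes a different computational path from the package implementation.

# Single-locus Wright-Fisher simulation (binomial sampling + symmetric
# mutation, no recombination or linkage): the distribution of one site's
# allele frequency under the same epoch schedule and terminal expansion as
# the haplotype burn-in. Returns the final sample frequency per locus.
wf_oracle_freqs <- function(n_loci, epochs, u, n_out, seed) {
  set.seed(seed)
  p <- numeric(n_loci)
  step <- function(p, n_alleles) {
    x <- rbinom(n_loci, n_alleles, p)
    x <- x + rbinom(n_loci, n_alleles - x, u) - rbinom(n_loci, x, u)
    x / n_alleles
  }
  for (e in seq_len(nrow(epochs))) {
    for (g in seq_len(epochs$generations[e])) {
      p <- step(p, 2L * epochs$ne[e])
    }
  }
  step(p, n_out)
}

# Recursive kinship (coefficient of coancestry) with memoisation; the
# relationship matrix is A = 2 * phi. Top-down recursion, unlike the
# bottom-up tabular loop in the package.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(s[i], d[i]))
    } else {
      # j is the younger one (pedigree is ordered)
      0.5 * (phi(i, s[j]) + phi(i, d[j]))
    }
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# Dense mixed-model-equation solve by direct inversion, built from the
# covariance matrix K (not its inverse).
dense_mme_oracle <- function(y, record_animal, K, lambda) {
  n <- nrow(K)
  nr <- length(y)
  Z <- matrix(0, nr, n)
  Z[cbind(seq_len(nr), record_animal)] <- 1
  X <- matrix(1, nr, 1)
  W <- cbind(X, Z)
  LHS <- crossprod(W)
  LHS[-1, -1] <- LHS[-1, -1] + lambda * solve(K)
  sol <- solve(LHS, crossprod(W, y))
  list(mu = sol[1], ebv = sol[-1])
}

# random valid pedigree: n_founders founders then n_extra animals whose
# parents are drawn from earlier animals (opposite sexes enforced)
random_pedigree <- function(n_founders, n_extra, seed) {
  set.seed(seed)
  n <- n_founders + n_extra
  sex <- c(rep(c("F", "M"), length.out = n_founders),
           sample(c("F", "M"), n_extra, replace = TRUE))
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    sire[i] <- if (length(males)) sample(males, 1) else 0L
    dam[i] <- if (length(females)) sample(females, 1) else 0L
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex,
             generation = c(rep(0L, n_founders), seq_len(n_extra)))
}
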