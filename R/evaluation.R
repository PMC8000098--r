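#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen-Luo style computation via the tabular relationship recursion,
#' processed generation-wise: founders (unknown parents) have F = 0, and
#' F_i = A(s_i, d_i) / 2 for known parents. The pedigree must be
#' topologically ordered (parents before offspring).
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0 = unknown),
#'   topologically ordered.
#' @return numeric vector of inbreeding coefficients, one per pedigree row.
#' @export
inbreeding <- function(ped) {
  unname(diag(tabular_a(ped))) - 1
}

#' Dense pedigree relationship matrix (tabular method)
#'
#' Builds the full additive (numerator) relationship matrix A by the tabular
#' recursion: A_ij = (A_{j,s_i} + A_{j,d_i}) / 2 for j < i and
#' A_ii = 1 + A_{s_i, d_i} / 2, with unknown parents contributing zero.
#'
#' @param ped data.frame with `id`, `sire`, `dam` (0 = unknown),
#'   topologically ordered.
#' @return dense numeric matrix (n x n) with dimnames = ids.
#' @export
tabular_a <- function(ped) {
  idx <- match(ped$sire, ped$id, nomatch = 0L)
  idy <- match(ped$dam, ped$id, nomatch = 0L)
  A <- tryCatch(.tabular_a_cpp(idx - 1L, idy - 1L), error = function(e)
    stop("tabular_a: ", conditionMessage(e)))
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes at most nine
#' nonzeros through its Mendelian-sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one known) or `1` (founders).
#'
#' @param ped data.frame with `id`, `sire`, `dam` (0 = unknown),
#'   topologically ordered.
#' @param F inbreeding coefficients per animal; computed via [inbreeding()]
#'   when `NULL`.
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = ids.
#' @export
a_inverse <- function(ped, F = NULL) {
  n <- nrow(ped)
  if (is.null(F)) F <- inbreeding(ped)
  stopifnot(length(F) == n)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one <- xor(s > 0L, d > 0L)
  dms <- ifelse(both, 0.5 - 0.25 * (Fs + Fd),
                ifelse(one, 0.75 - 0.25 * (Fs + Fd), 1))
  al <- 1 / dms
  i <- seq_len(n)
  # triplet lists; duplicates are summed by sparseMatrix
  ti <- c(i, s[both], d[both], i[both], i[both], s[both], d[both],
          s[both], d[both],
          s[one] + d[one], i[one], s[one] + d[one])
  tj <- c(i, s[both], d[both], s[both], d[both], i[both], i[both],
          d[both], s[both],
          s[one] + d[one], s[one] + d[one], i[one])
  tx <- c(al, al[both] / 4, al[both] / 4, -al[both] / 2, -al[both] / 2,
          -al[both] / 2, -al[both] / 2, al[both] / 4, al[both] / 4,
          al[one] / 4, -al[one] / 2, -al[one] / 2)
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(M)
}

#' VanRaden genomic relationship matrix
#'
#' `G0 = M M' / (2 sum p_j (1 - p_j))` with `M` the allele-frequency-centred
#' dosage matrix. When `a22` is supplied the result is blended,
#' `G = (1 - blend) G0 + blend A22`, which guarantees invertibility of G in
#' the single-step system.
#'
#' @param dosages numeric matrix (animals x markers), dosages in \[0, 2\]
#'   (fractional imputed dosages allowed), no missing values.
#' @param p allele frequencies used for centring; observed column means / 2
#'   when `NULL`.
#' @param a22 optional pedigree relationship block of the genotyped animals
#'   (same order) for blending.
#' @param blend weight given to `a22` in the blend.
#' @return dense genomic relationship matrix.
#' @export
g_matrix <- function(dosages, p = NULL, a22 = NULL, blend = 0.05) {
  stopifnot(!anyNA(dosages))
  if (is.null(p)) p <- colMeans(dosages) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("g_matrix: sum p(1-p) is zero; no segregating markers")
  M <- sweep(dosages, 2L, 2 * p)
  G0 <- tcrossprod(M) / denom
  if (is.null(a22)) {
    return(G0)
  }
  stopifnot(all(dim(a22) == dim(G0)))
  (1 - blend) * G0 + blend * a22
}

#' Quality control of a genotype matrix
#'
#' Standard pre-G filters on hard calls: drop markers with minor allele
#' frequency below `maf_min` or call rate below `site_call_min`, then drop
#' animals with call rate below `animal_call_min` on the retained markers.
#'
#' @param hard matrix (animals x markers) of hard calls 0/1/2 with NA for
#'   no-calls.
#' @param maf_min minimum minor allele frequency.
#' @param site_call_min minimum per-marker call rate.
#' @param animal_call_min minimum per-animal call rate.
#' @return list with logical `keep_sites`, `keep_animals` and a `report`
#'   data.frame of exclusion counts.
#' @export
qc_genotypes <- function(hard, maf_min = 0.05, site_call_min = 0.90,
                         animal_call_min = 0.90) {
  cr_site <- colMeans(!is.na(hard))
  p <- colMeans(hard, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_sites <- cr_site >= site_call_min & maf >= maf_min
  if (!any(keep_sites)) stop("qc_genotypes: all markers filtered out")
  cr_animal <- rowMeans(!is.na(hard[, keep_sites, drop = FALSE]))
  keep_animals <- cr_animal >= animal_call_min
  if (!any(keep_animals)) stop("qc_genotypes: all animals filtered out")
  list(keep_sites = keep_sites, keep_animals = keep_animals,
       report = data.frame(
         sites_total = ncol(hard), sites_removed = sum(!keep_sites),
         animals_total = nrow(hard), animals_removed = sum(!keep_animals)))
}

#' Single-step H-inverse
#'
#' Combines the sparse pedigree inverse with the genomic information of the
#' genotyped subset: `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, the correction
#' block placed on the genotyped animals' indices.
#'
#' @param a_inv sparse pedigree inverse over all animals.
#' @param G blended genomic relationship matrix of the genotyped animals.
#' @param a22 pedigree relationship block of the genotyped animals.
#' @param idx integer positions of the genotyped animals in the pedigree
#'   (same order as rows of `G`).
#' @return sparse symmetric matrix H^-1.
#' @export
h_inverse <- function(a_inv, G, a22, idx) {
  n <- nrow(a_inv)
  if (length(idx) == 0L) {
    return(a_inv)
  }
  stopifnot(nrow(G) == length(idx), all(dim(G) == dim(a22)))
  Gi <- tryCatch(solve(G), error = function(e)
    stop("h_inverse: G is singular; increase the blending weight ",
         "towards A22 (", conditionMessage(e), ")"))
  corr <- Gi - solve(a22)
  ii <- rep(idx, times = length(idx))
  jj <- rep(idx, each = length(idx))
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(corr),
                            dims = c(n, n))
  Matrix::forceSymmetric(a_inv + B)
}

#' Solve the single-trait animal-model mixed-model equations
#'
#' The model is `y = 1 mu + Z a + e` with `a ~ N(0, K sigma_a2)` and
#' `e ~ N(0, I sigma_e2)`; the MME are solved with a sparse Cholesky
#' factorisation:
#' `[1'1  1'Z; Z'1  Z'Z + lambda K^-1] [mu; a] = [1'y; Z'y]`.
#' EBVs are returned for every animal in the pedigree, including unphenotyped
#' candidates (information flows through K^-1).
#'
#' @param y numeric vector of phenotypic records.
#' @param record_animal integer positions (1-based, into the pedigree) of the
#'   animal each record belongs to.
#' @param K_inv sparse inverse covariance structure (A^-1 or H^-1).
#' @param lambda variance ratio sigma_e2 / sigma_a2.
#' @param method tag stored on the output ("BLUP" or "ssGBLUP").
#' @return list with `mu` (fixed-effect estimate), `ebv` (named by pedigree
#'   position dimnames of K_inv) and `method`.
#' @export
solve_mme <- function(y, record_animal, K_inv, lambda, method = "BLUP") {
  n <- nrow(K_inv)
  nr <- length(y)
  stopifnot(length(record_animal) == nr, lambda > 0,
            all(record_animal >= 1L & record_animal <= n))
  Z <- Matrix::sparseMatrix(i = seq_len(nr), j = record_animal, x = 1,
                            dims = c(nr, n))
  W <- cbind(Matrix::Matrix(1, nr, 1, sparse = TRUE), Z)
  LHS <- Matrix::crossprod(W) +
    Matrix::bdiag(Matrix::Matrix(0, 1, 1), lambda * K_inv)
  rhs <- as.vector(Matrix::crossprod(W, y))
  LHS <- Matrix::forceSymmetric(methods::as(LHS, "CsparseMatrix"))
  sol <- tryCatch(
    as.vector(Matrix::solve(Matrix::Cholesky(LHS, LDL = FALSE, perm = TRUE),
                            rhs)),
    error = function(e) stop("solve_mme: MME system could not be factorised (",
                             conditionMessage(e), ")"))
  ebv <- sol[-1L]
  names(ebv) <- rownames(K_inv)
  list(mu = sol[1L], ebv = ebv, method = method)
}

#' Parent-average EBVs for non-genotyped candidates
#'
#' `EBV = (EBV_sire + EBV_dam) / 2`; used to rank the non-genotyped half of
#' the candidate cohort in the half-genotyped scenario.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @param ebv named numeric vector of EBVs (names = ids).
#' @param ids candidates to compute parent averages for.
#' @return numeric vector, one per candidate.
#' @export
parent_average_ebv <- function(ped, ebv, ids) {
  r <- match(ids, ped$id)
  stopifnot(!anyNA(r))
  s <- ped$sire[r]; d <- ped$dam[r]
  if (any(s == 0L | d == 0L)) {
    stop("parent_average_ebv: candidate with unknown parent")
  }
  es <- ebv[as.character(s)]
  ed <- ebv[as.character(d)]
  if (anyNA(es) || anyNA(ed)) {
    stop("parent_average_ebv: parent without an EBV")
  }
  unname((es + ed) / 2)
}
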