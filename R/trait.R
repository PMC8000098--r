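#' Trait architecture for litter size
#'
#' QTN positions, additive effects and variance scaling for the simulated
#' trait. Effects have Gamma-distributed magnitudes (shape 0.60, scale 0.80)
#' with random signs; after scaling, the additive variance of true breeding
#' values (TBVs) in the founder population equals `target_base_variance` and
#' the residual variance follows from the heritability,
#' `sigma_e2 = sigma_a2 * (1 - h2) / h2`.
#'
#' @name trait_architecture
NULL

#' Sample QTN positions
#'
#' Chooses `qtn_per_chromosome` QTNs at random from the segregating sites of
#' each chromosome (equal count per chromosome). 44 per chromosome gives the
#' highly polygenic model (880 QTNs over 20 chromosomes), 5 per chromosome the
#' sparse one (100 QTNs).
#'
#' @param flat flattened pool from [flatten_pool()].
#' @param qtn_per_chromosome QTN count per chromosome (all chromosomes equal).
#' @param h2 heritability of the trait.
#' @param target_base_variance additive variance to impose on founder TBVs.
#' @param gamma_shape,gamma_scale parameters of the effect-magnitude Gamma.
#' @param mu population mean of the phenotype (litter size, kits).
#' @param seed integer seed.
#' @return a `trait_architecture` with positions only (no effects yet).
#' @export
sample_qtns <- function(flat, qtn_per_chromosome, h2 = 0.113,
                        target_base_variance = 0.675,
                        gamma_shape = 0.60, gamma_scale = 0.80,
                        mu = 10, seed = NULL) {
  stopifnot(qtn_per_chromosome >= 1, h2 > 0, h2 < 1)
  .seed_if(seed)
  chroms <- sort(unique(flat$site_chr))
  idx <- integer(0)
  for (cc in chroms) {
    sites <- which(flat$site_chr == cc)
    if (length(sites) < qtn_per_chromosome) {
      stop(sprintf(paste0("sample_qtns: chromosome %d has %d segregating ",
                          "sites, %d QTNs requested"),
                   cc, length(sites), qtn_per_chromosome))
    }
    idx <- c(idx, sort(sample(sites, qtn_per_chromosome)))
  }
  arch <- list(qtn_idx = idx,
               qtn_chr = flat$site_chr[idx],
               qtn_freq = flat$freq[idx],
               qtn_per_chromosome = as.integer(qtn_per_chromosome),
               effects = NULL,
               gamma_shape = gamma_shape, gamma_scale = gamma_scale,
               target_base_variance = target_base_variance,
               h2 = h2, sigma_a2 = NA_real_, sigma_e2 = NA_real_,
               scaling_constant = NA_real_, mu = mu)
  class(arch) <- "trait_architecture"
  arch
}

#' Sample additive QTN effects
#'
#' Magnitudes are Gamma(shape, scale) draws; signs are independent fair coin
#' flips (the Gamma is positive-valued, so symmetric signs avoid a directional
#' founder bias).
#'
#' @param arch a `trait_architecture` with positions sampled.
#' @param seed integer seed.
#' @return the architecture with unscaled `effects`.
#' @export
sample_effects <- function(arch, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  .seed_if(seed)
  n <- length(arch$qtn_idx)
  mag <- stats::rgamma(n, shape = arch$gamma_shape, scale = arch$gamma_scale)
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  arch$effects <- mag * sgn
  arch$scaling_constant <- NA_real_
  arch
}

#' Scale effects so founder TBV variance hits the base additive variance
#'
#' Multiplies all effects by one constant so the sample variance of TBVs over
#' the founder diploids equals `target_base_variance` exactly, and sets the
#' residual variance from the heritability. Applying it twice is a no-op.
#'
#' @param arch a `trait_architecture` with effects sampled.
#' @param founder_qtn_dosages integer matrix (founders x QTNs) of dosages
#'   0/1/2 at the QTN sites.
#' @return the architecture with scaled effects, `sigma_a2`, `sigma_e2` and
#'   `scaling_constant` set.
#' @export
scale_variances <- function(arch, founder_qtn_dosages) {
  stopifnot(inherits(arch, "trait_architecture"), !is.null(arch$effects))
  raw <- true_breeding_value(founder_qtn_dosages, arch)
  v <- stats::var(raw)
  if (!is.finite(v) || v <= 0) {
    stop("scale_variances: founder TBV variance is zero (all QTNs fixed ",
         "or all effects zero); cannot scale")
  }
  k <- sqrt(arch$target_base_variance / v)
  arch$effects <- arch$effects * k
  arch$scaling_constant <- k
  arch$sigma_a2 <- arch$target_base_variance
  arch$sigma_e2 <- arch$sigma_a2 * (1 - arch$h2) / arch$h2
  arch
}

#' True breeding value from QTN dosages
#'
#' Additive model: `TBV = sum_q (dosage_q - 2 p_q) * effect_q`, with `p_q`
#' the founder allele frequency, so founder TBVs are centred near zero.
#'
#' @param qtn_dosages matrix (individuals x QTNs) of dosages in 0/1/2, or a
#'   single dosage vector.
#' @param arch a `trait_architecture` with effects.
#' @return numeric vector of TBVs.
#' @export
true_breeding_value <- function(qtn_dosages, arch) {
  stopifnot(inherits(arch, "trait_architecture"), !is.null(arch$effects))
  if (is.null(dim(qtn_dosages))) qtn_dosages <- matrix(qtn_dosages, nrow = 1)
  if (anyNA(qtn_dosages)) stop("true_breeding_value: missing QTN dosage")
  stopifnot(ncol(qtn_dosages) == length(arch$effects))
  ctr <- sweep(qtn_dosages, 2L, 2 * arch$qtn_freq)
  as.vector(ctr %*% arch$effects)
}

#' Phenotypes for a cohort (sex-limited expression)
#'
#' Litter size is recorded on does only: females get
#' `y = mu + TBV + N(0, sigma_e2)`, males get `NA`.
#'
#' @param sex character vector of "F"/"M".
#' @param tbv numeric vector of true breeding values.
#' @param arch a scaled `trait_architecture`.
#' @param seed integer seed.
#' @return numeric vector (NA for males).
#' @export
sample_phenotypes <- function(sex, tbv, arch, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"), is.finite(arch$sigma_e2),
            length(sex) == length(tbv))
  .seed_if(seed)
  y <- rep(NA_real_, length(sex))
  f <- sex == "F"
  y[f] <- arch$mu + tbv[f] +
    stats::rnorm(sum(f), sd = sqrt(arch$sigma_e2))
  y
}

#' Write a trait architecture to a plain-text table
#'
#' @param arch a `trait_architecture`.
#' @param path output path (tab-separated: chromosome, site index, frequency,
#'   effect).
#' @return invisibly, the path.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "trait_architecture"))
  utils::write.table(
    data.frame(chromosome = arch$qtn_chr, site = arch$qtn_idx,
               founder_freq = arch$qtn_freq,
               effect = if (is.null(arch$effects)) NA else arch$effects),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method base::print
#' @noRd
print.trait_architecture <- function(x, ...) {
  cat("trait_architecture:", length(x$qtn_idx), "QTNs (",
      x$qtn_per_chromosome, "per chromosome ), h2 =", x$h2,
      ", sigma_a2 =", x$sigma_a2, ", sigma_e2 =", round(x$sigma_e2, 4), "\n")
  invisible(x)
}
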