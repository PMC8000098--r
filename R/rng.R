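#' Derive a child seed from a root seed and a stream label
#'
#' Simulation stages (founders, trait architecture, gene drop, masking, ...)
#' draw from independent streams derived deterministically from one root seed,
#' so that any stage can be re-run in isolation and replicates never share a
#' stream. The derivation is a polynomial hash of the label folded into the
#' root seed modulo 2^31 - 1, which keeps results inside R's integer range.
#'
#' @param seed integer root seed.
#' @param ... label components (coerced to character) identifying the stream,
#'   e.g. `derive_seed(42, "founders", chrom = 3)`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  mix <- (as.numeric(seed %% m) * 48271 + h + 1) %% m
  as.integer(mix)
}

# set.seed() only when a seed was given
.seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
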