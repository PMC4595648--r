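#' Round half away from zero
#'
#' Reporting convention for fractional abundances and percentages: ties round
#' up in magnitude (13.25 -> 13.3), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(80.95, 0) # 81
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp so values like 21.2121... * 10 = 212.12 are untouched but
  # exact .5 representations round up despite binary underestimation
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable sub-stream seed derived from a master seed and a key tuple, so that
# e.g. adding zones to a simulated cohort never perturbs the draws of
# existing (patient, zone, locus) streams.  Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

# stop() with a consistent prefix-free message; `field` names the offending
# config/argument field so validation errors are self-describing.
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

locus_key <- function(contig, pos) paste(contig, pos, sep = ":")

variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}
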