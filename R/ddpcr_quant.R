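#' Poisson concentration estimate for one ddPCR channel
#'
#' With `k` positive droplets of `n`, the mean template occupancy per
#' droplet is `lambda = -ln(1 - k/n)`; dividing by the droplet volume gives
#' copies per microlitre (`lambda / v * 1000` for `v` in nl). The 95% CI is
#' a delta-method interval on lambda: `SE(lambda) = sqrt(k / (n (n - k)))`,
#' `lambda +- 1.96 SE`, floored at 0, then scaled. This is an approximation
#' to instrument-software intervals, whose exact method is unpublished.
#'
#' @param count one-row droplet count (columns `droplets_total`,
#'   `mutant_positive`, `wildtype_positive`, `droplet_volume_nl`, as from
#'   [simulate_droplets()] or [read_droplet_tsv()]).
#' @param channel `"mutant"` or `"wildtype"`.
#' @return a `concentration_estimate` list: `copies_per_ul`, `ci_low`,
#'   `ci_high`, `lambda`, `se_lambda`, `channel`.
#' @export
estimate_concentration <- function(count, channel = c("mutant", "wildtype")) {
  channel <- match.arg(channel)
  n <- count$droplets_total
  k <- if (channel == "mutant") count$mutant_positive else count$wildtype_positive
  v <- count$droplet_volume_nl
  if (length(n) != 1 || k < 0 || k > n) fail_field("count", "requires 0 <= k <= n")
  if (v <= 0) fail_field("droplet_volume_nl", "must be > 0")
  if (k == n) {
    stop("all droplets positive: occupancy saturated, lambda undefined", call. = FALSE)
  }
  lambda <- -log(1 - k / n)
  se <- sqrt(k / (n * (n - k)))
  scale <- 1000 / v  # copies/droplet -> copies/ul for v in nl
  structure(list(copies_per_ul = lambda * scale,
                 ci_low = max(0, lambda - 1.96 * se) * scale,
                 ci_high = (lambda + 1.96 * se) * scale,
                 lambda = lambda, se_lambda = se, channel = channel),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("%s channel: %.2f copies/ul (95%% CI %.2f-%.2f)\n",
              x$channel, x$copies_per_ul, x$ci_low, x$ci_high))
  invisible(x)
}

#' Mutant fractional abundance from channel concentrations
#'
#' `100 x c_m / (c_m + c_w)` with a delta-method CI propagating both
#' channel standard errors.
#'
#' @param mut,wt `concentration_estimate`s for the mutant and wild-type
#'   channels of the same well.
#' @return list with `fraction_pct`, `ci_low`, `ci_high`.
#' @export
ddpcr_fractional_abundance <- function(mut, wt) {
  stopifnot(inherits(mut, "concentration_estimate"),
            inherits(wt, "concentration_estimate"))
  cm <- mut$copies_per_ul
  cw <- wt$copies_per_ul
  if (cm + cw <= 0) {
    stop("fractional abundance undefined: both channels at zero concentration",
         call. = FALSE)
  }
  f <- cm / (cm + cw)
  # delta method on f(cm, cw); SE(conc) = SE(lambda) x the volume scale,
  # recovered as conc/lambda (SE is 0 whenever lambda is 0)
  var_cm <- if (mut$lambda > 0) (mut$se_lambda * cm / mut$lambda)^2 else 0
  var_cw <- if (wt$lambda > 0) (wt$se_lambda * cw / wt$lambda)^2 else 0
  se_f <- sqrt(cw^2 * var_cm + cm^2 * var_cw) / (cm + cw)^2
  list(fraction_pct = 100 * f,
       ci_low = 100 * max(0, f - 1.96 * se_f),
       ci_high = 100 * min(1, f + 1.96 * se_f))
}

#' Detection call for one ddPCR well
#'
#' A mutation is called detected iff at least `min_positive_droplets`
#' droplets are mutant-positive (default 3; instrument pipelines do not
#' publish a criterion, so this is configurable).
#'
#' @param count one-row droplet count.
#' @param min_positive_droplets detection threshold.
#' @return logical.
#' @export
detect_mutant <- function(count, min_positive_droplets = 3) {
  count$mutant_positive >= min_positive_droplets
}

#' Limit of detection from a simulated serial-dilution series
#'
#' For each mutant fraction, simulates `replicates` ddPCR wells
#' ([simulate_droplets()]) and applies [detect_mutant()]; the limit of
#' detection is the smallest fraction whose detection rate reaches
#' `detect_rate_required`.
#'
#' @param config a [simulation_config()] (droplet count, volume, template
#'   copies, master seed).
#' @param fractions_pct mutant fractions in percent, sorted descending.
#' @param replicates wells per fraction.
#' @param detect_rate_required required detection rate (default 0.95).
#' @param min_positive_droplets detection threshold per well.
#' @return list with `lod_pct` (smallest reliably detected fraction, `NA`
#'   if none, with attribute `"censored"` = `"above max fraction tested"`)
#'   and `rates` (data frame of per-fraction detection rates).
#' @export
lod_series <- function(config, fractions_pct = c(5, 1, 0.5, 0.1),
                       replicates = 200, detect_rate_required = 0.95,
                       min_positive_droplets = 3) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.unsorted(rev(fractions_pct))) {
    fail_field("fractions_pct", "must be sorted descending")
  }
  if (!is_count(replicates, min = 1)) fail_field("replicates", "must be >= 1")
  rates <- vapply(seq_along(fractions_pct), function(i) {
    hits <- vapply(seq_len(replicates), function(r) {
      seed <- derive_seed(config$random_seed, "lod", fractions_pct[i], r)
      cnt <- simulate_droplets(fractions_pct[i], config, seed = seed)
      detect_mutant(cnt, min_positive_droplets)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  ok <- which(rates >= detect_rate_required)
  lod <- if (length(ok)) min(fractions_pct[ok]) else
    structure(NA_real_, censored = "above max fraction tested")
  list(lod_pct = lod,
       rates = data.frame(fraction_pct = fractions_pct, detection_rate = rates))
}

#' NGS vs ddPCR fluid concordance table
#'
#' Joins NGS tissue calls with per-compartment droplet results into one row
#' per mutation: detection flags and fractional abundances for each
#' compartment, plus per-compartment detected totals.
#'
#' @param ngs_calls data frame with columns `mutation_id` and optionally
#'   `fractional_abundance` (tissue percent); every mutation tested must
#'   appear here.
#' @param droplet_results data frame of droplet counts with columns
#'   `mutation_id`, `compartment` (e.g. `"plasma"`, `"sputum"`) plus the
#'   [simulate_droplets()] count columns. One row per
#'   (mutation, compartment).
#' @param min_positive_droplets detection threshold per well.
#' @return list with `table` (one row per mutation: `detected_ngs` flag,
#'   per-compartment `detected_*` flags and `abundance_*_pct`) and `totals`
#'   (named counts of detected mutations per compartment).
#' @export
ddpcr_concordance <- function(ngs_calls, droplet_results,
                              min_positive_droplets = 3) {
  if (!all(c("mutation_id", "compartment") %in% names(droplet_results))) {
    fail_field("droplet_results", "requires columns mutation_id, compartment")
  }
  key <- paste(droplet_results$mutation_id, droplet_results$compartment)
  if (anyDuplicated(key)) {
    fail_field("droplet_results", "duplicate (mutation, compartment) entries")
  }
  if (!all(droplet_results$mutation_id %in% ngs_calls$mutation_id)) {
    fail_field("droplet_results", "mutation ids absent from ngs_calls")
  }
  muts <- unique(ngs_calls$mutation_id)
  comps <- unique(droplet_results$compartment)
  tab <- data.frame(mutation_id = muts,
                    detected_ngs = muts %in% ngs_calls$mutation_id,
                    stringsAsFactors = FALSE)
  if ("fractional_abundance" %in% names(ngs_calls)) {
    tab$abundance_ngs_pct <- ngs_calls$fractional_abundance[match(muts, ngs_calls$mutation_id)]
  }
  for (cp in comps) {
    det <- rep(FALSE, length(muts))
    ab <- rep(NA_real_, length(muts))
    rows <- droplet_results[droplet_results$compartment == cp, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      j <- match(rows$mutation_id[i], muts)
      cnt <- rows[i, , drop = FALSE]
      det[j] <- detect_mutant(cnt, min_positive_droplets)
      if (cnt$mutant_positive < cnt$droplets_total &&
          cnt$wildtype_positive < cnt$droplets_total &&
          cnt$mutant_positive + cnt$wildtype_positive > 0) {
        m <- estimate_concentration(cnt, "mutant")
        w <- estimate_concentration(cnt, "wildtype")
        if (m$copies_per_ul + w$copies_per_ul > 0) {
          ab[j] <- ddpcr_fractional_abundance(m, w)$fraction_pct
        }
      }
    }
    tab[[paste0("detected_", cp)]] <- det
    tab[[paste0("abundance_", cp, "_pct")]] <- ab
  }
  totals <- stats::setNames(
    vapply(comps, function(cp) sum(tab[[paste0("detected_", cp)]]), integer(1)),
    comps)
  list(table = tab, totals = totals)
}
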