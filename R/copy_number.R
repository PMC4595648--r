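#' Normalize a per-gene coverage profile
#'
#' Divides each gene's average per-base coverage by the sample-wide mean
#' (or median) gene coverage, so profiles from samples sequenced to
#' different depths become comparable.
#'
#' @param profile data frame with columns `gene` and `avg_depth`, or a named
#'   numeric vector of coverages.
#' @param center `"mean"` (default, the plain reading of a normalized
#'   average) or `"median"` for robustness to a few high-amplitude genes.
#' @return data frame with columns `gene`, `avg_depth`, `normalized`; the
#'   normalization constant is attached as attribute `"center"`.
#' @export
normalize_coverage <- function(profile, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.numeric(profile) && !is.null(names(profile))) {
    profile <- data.frame(gene = names(profile), avg_depth = unname(profile),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("gene", "avg_depth") %in% names(profile))) {
    fail_field("profile", "requires columns gene, avg_depth")
  }
  if (any(profile$avg_depth < 0)) fail_field("avg_depth", "coverages must be >= 0")
  if (all(profile$avg_depth == 0)) fail_field("profile", "all-zero coverage profile")
  cst <- if (center == "mean") mean(profile$avg_depth) else stats::median(profile$avg_depth)
  out <- data.frame(gene = profile$gene, avg_depth = profile$avg_depth,
                    normalized = profile$avg_depth / cst, stringsAsFactors = FALSE)
  attr(out, "center") <- cst
  out
}

#' Call per-gene copy-number alterations from coverage ratios
#'
#' For each panel gene the normalized tumour coverage is divided by the
#' normalized matched-normal coverage; genes at or above `amp_threshold`
#' are amplifications, at or below `del_threshold` deletions, otherwise
#' neutral. Expected ratio for a gene at `n` copies in a tumour of purity
#' `p` (diploid background) is `1 + p (n - 2) / 2`, so default thresholds of
#' 2.0 / 0.5 (log2 +-1) demand high-level events.
#'
#' @param tumor,normal coverage profiles ([normalize_coverage()] input
#'   forms); normalized internally with `center`.
#' @param amp_threshold ratio at or above which a gene is called amplified.
#' @param del_threshold ratio at or below which a gene is called deleted.
#' @param center normalization center, see [normalize_coverage()].
#' @return data frame: `gene`, `ratio`, `log2`, `class`
#'   (`"amplification"`/`"deletion"`/`"neutral"`).
#' @export
call_cna <- function(tumor, normal, amp_threshold = 2.0, del_threshold = 0.5,
                     center = c("mean", "median")) {
  center <- match.arg(center)
  t_norm <- normalize_coverage(tumor, center)
  n_norm <- normalize_coverage(normal, center)
  if (!setequal(t_norm$gene, n_norm$gene)) {
    diff <- c(setdiff(t_norm$gene, n_norm$gene), setdiff(n_norm$gene, t_norm$gene))
    stop(sprintf("tumor/normal gene sets differ: %s", paste(diff, collapse = ", ")),
         call. = FALSE)
  }
  n_norm <- n_norm[match(t_norm$gene, n_norm$gene), ]
  if (any(n_norm$normalized == 0)) {
    fail_field("normal", "zero normalized coverage for some gene")
  }
  ratio <- t_norm$normalized / n_norm$normalized
  class <- ifelse(ratio >= amp_threshold, "amplification",
                  ifelse(ratio <= del_threshold, "deletion", "neutral"))
  data.frame(gene = t_norm$gene, ratio = ratio, log2 = log2(ratio),
             class = class, stringsAsFactors = FALSE)
}
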