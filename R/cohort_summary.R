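#' Per-lesion mutation rate
#'
#' Mean number of non-synonymous somatic calls per lesion (one decimal for
#' reporting) and the range of per-lesion counts.
#'
#' @param calls_per_lesion named list, lesion -> call data frame (accepted
#'   calls; `status`/`consequence` columns honoured as in [build_matrix()]),
#'   or a numeric vector of per-lesion counts.
#' @return list with `mean` (one decimal), `min`, `max`, `total`,
#'   `n_lesions`, and `counts` (named per-lesion counts).
#' @examples
#' mutation_rate(c(3, 0, 6))  # mean 3.0, range 0-6
#' @export
mutation_rate <- function(calls_per_lesion) {
  if (length(calls_per_lesion) == 0) {
    fail_field("calls_per_lesion", "at least one lesion is required")
  }
  counts <- if (is.numeric(calls_per_lesion)) {
    calls_per_lesion
  } else {
    vapply(calls_per_lesion, function(d) {
      if (is.null(d) || nrow(d) == 0) return(0L)
      keep <- if ("status" %in% names(d)) d$status == "accepted" else rep(TRUE, nrow(d))
      if ("consequence" %in% names(d)) {
        keep <- keep & (is.na(d$consequence) | !d$consequence %in% c("silent", "intronic"))
      }
      sum(keep)
    }, integer(1))
  }
  list(mean = round_half_up(sum(counts) / length(counts), 1),
       min = min(counts), max = max(counts),
       total = sum(counts), n_lesions = length(counts), counts = counts)
}

#' Directional base-substitution spectrum
#'
#' Counts SNVs in the 12 directional reference-to-alternate classes (A>C,
#' A>G, ..., T>G). Classes are kept directional, not collapsed to the six
#' pyrimidine-context pairs, because panel studies report e.g. G-A and C-T
#' separately. Silent calls are excluded; indels and non-ACGT alleles are
#' skipped and counted in the `n_indels` / `n_skipped` attributes.
#'
#' @param calls data frame of calls with `ref`, `alt` (and optionally
#'   `status` / `consequence` columns, honoured as elsewhere).
#' @return a `substitution_spectrum`: named integer vector of the 12 class
#'   counts with attributes `total`, `n_indels`, `n_skipped`.
#' @export
substitution_spectrum <- function(calls) {
  bases <- c("A", "C", "G", "T")
  classes <- as.vector(outer(bases, bases, function(r, a) paste0(r, ">", a)))
  classes <- classes[substr(classes, 1, 1) != substr(classes, 3, 3)]
  counts <- stats::setNames(integer(length(classes)), sort(classes))
  n_indels <- 0L
  n_skipped <- 0L
  if (nrow(calls) > 0) {
    keep <- if ("status" %in% names(calls)) calls$status == "accepted" else rep(TRUE, nrow(calls))
    if ("consequence" %in% names(calls)) {
      keep <- keep & (is.na(calls$consequence) | calls$consequence != "silent")
    }
    calls <- calls[keep, , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      ref <- calls$ref[i]
      alt <- calls$alt[i]
      if (nchar(ref) != 1 || nchar(alt) != 1 || ref == "-" || alt == "-") {
        n_indels <- n_indels + 1L
        next
      }
      if (!ref %in% bases || !alt %in% bases) {
        warning(sprintf("non-ACGT SNV alleles %s>%s skipped", ref, alt))
        n_skipped <- n_skipped + 1L
        next
      }
      cls <- paste0(ref, ">", alt)
      counts[cls] <- counts[cls] + 1L
    }
  }
  structure(counts, total = sum(counts), n_indels = n_indels,
            n_skipped = n_skipped, class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("substitution_spectrum: %d SNV(s) (%d indel(s) ignored)\n",
              attr(x, "total"), attr(x, "n_indels")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Partition genes by stage-membership signature
#'
#' Assigns every gene its exact membership signature across histologic
#' stages (which of AAH / AIS / MIA / PRIMARY carry a mutation in it); the
#' cell of genes mutated in all stages is reported explicitly.
#'
#' @param stage_gene_sets named list, stage label -> character vector of
#'   mutated genes. Stage names must come from
#'   `c("AAH", "AIS", "MIA", "PRIMARY")`.
#' @return list with `partition` (signature such as `"AAH+MIA"` -> genes)
#'   and `all_stages` (genes mutated in every supplied stage).
#' @export
stage_overlap <- function(stage_gene_sets) {
  stages <- names(stage_gene_sets)
  if (length(stages) < 2) fail_field("stage_gene_sets", "at least two stages required")
  if (!all(stages %in% c("AAH", "AIS", "MIA", "PRIMARY"))) {
    fail_field("stage_gene_sets", "stage labels must be AAH, AIS, MIA or PRIMARY")
  }
  genes <- sort(unique(unlist(stage_gene_sets, use.names = FALSE)))
  sig <- vapply(genes, function(g) {
    paste(stages[vapply(stage_gene_sets, function(s) g %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  partition <- split(genes, sig)
  all_sig <- paste(stages, collapse = "+")
  list(partition = partition,
       all_stages = if (all_sig %in% names(partition)) partition[[all_sig]] else character())
}

#' Fractional-abundance progression from precursor lesions to primary tumour
#'
#' A mutation's row lists fractional abundances across samples in their
#' listed order, ending at the primary tumour. A row is "increasing" iff the
#' primary abundance strictly exceeds every earlier abundance and the
#' earlier abundances are non-decreasing in order (flat interior steps
#' allowed).
#'
#' @param table data frame with columns `mutation`, `sample`,
#'   `abundance_pct`, `is_primary` (logical; exactly one primary per
#'   mutation, taken as the endpoint). Rows of one mutation are kept in
#'   their listed order.
#' @return list with `flags` (named logical per mutation) and `n_increasing`.
#' @export
abundance_progression <- function(table) {
  req <- c("mutation", "sample", "abundance_pct", "is_primary")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    fail_field("table", paste("requires columns", paste(req, collapse = ", ")))
  }
  if (any(table$abundance_pct < 0 | table$abundance_pct > 100)) {
    fail_field("abundance_pct", "must be in [0, 100]")
  }
  flags <- vapply(split(table, table$mutation)[unique(table$mutation)], function(d) {
    if (nrow(d) < 2) {
      stop(sprintf("mutation %s has fewer than 2 samples", d$mutation[1]), call. = FALSE)
    }
    if (sum(d$is_primary) != 1) {
      stop(sprintf("mutation %s must have exactly one primary sample", d$mutation[1]),
           call. = FALSE)
    }
    d <- rbind(d[!d$is_primary, , drop = FALSE], d[d$is_primary, , drop = FALSE])
    earlier <- d$abundance_pct[-nrow(d)]
    primary <- d$abundance_pct[nrow(d)]
    all(primary > earlier) && !is.unsorted(earlier)
  }, logical(1))
  list(flags = flags, n_increasing = sum(flags))
}
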