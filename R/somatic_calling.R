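#' Caller thresholds for matched tumour/normal somatic calling
#'
#' Defaults reflect the VariantDx-style rule set used for targeted panels:
#' a strict base-quality cut of phred > 30 in the tumour and > 20 in the
#' matched normal, at least 2 distinct alternate read pairs, a tumour
#' alternate fraction of at least 2% of total distinct read pairs, a matched
#' normal alternate fraction of at most 1%, and mapping quality >= 20
#' ("poorly mapped" reads excluded).
#'
#' @param tumor_phred_min minimum (exclusive) base phred in the tumour.
#' @param normal_phred_min minimum (exclusive) base phred in the normal.
#' @param tumor_fraction_min minimum tumour alternate fraction (inclusive).
#' @param normal_fraction_max maximum normal alternate fraction (inclusive).
#' @param min_alt_pairs minimum distinct alternate read pairs (inclusive).
#' @param min_mapq minimum mapping quality (inclusive).
#' @return a `caller_thresholds` list.
#' @export
caller_thresholds <- function(tumor_phred_min = 30, normal_phred_min = 20,
                              tumor_fraction_min = 0.02,
                              normal_fraction_max = 0.01,
                              min_alt_pairs = 2, min_mapq = 20) {
  if (!is_prob(tumor_fraction_min)) fail_field("tumor_fraction_min", "must be in [0, 1]")
  if (!is_prob(normal_fraction_max)) fail_field("normal_fraction_max", "must be in [0, 1]")
  if (!is_count(tumor_phred_min)) fail_field("tumor_phred_min", "must be a non-negative integer")
  if (!is_count(normal_phred_min)) fail_field("normal_phred_min", "must be a non-negative integer")
  if (!is_count(min_alt_pairs)) fail_field("min_alt_pairs", "must be a non-negative integer")
  structure(list(tumor_phred_min = tumor_phred_min,
                 normal_phred_min = normal_phred_min,
                 tumor_fraction_min = tumor_fraction_min,
                 normal_fraction_max = normal_fraction_max,
                 min_alt_pairs = min_alt_pairs,
                 min_mapq = min_mapq),
            class = "caller_thresholds")
}

#' Tally distinct read-pair observations into per-locus allele counts
#'
#' Applies the alignment and base-quality filters, then collapses read-pair
#' observations by fragment signature so each distinct pair counts once, and
#' tallies alternate and total distinct pairs per locus.
#'
#' Excluded observations: unpaired (`is_paired` false), quality-failed
#' (`is_quality_pass` false), mapping quality below `min_mapq`, and base
#' phred not strictly above the role's cutoff (> 30 tumour, > 20 normal).
#'
#' @param obs data frame of read-pair observations with columns `contig`,
#'   `pos`, `ref`, `allele` (the base observed by that read pair, equal to
#'   `ref` for reference-supporting pairs), `is_paired`, `is_quality_pass`,
#'   `mapq`, `min_phred` (minimum base phred across the variant site in the
#'   pair), `fragment_id` (fragment endpoint signature).
#' @param role `"tumor"` or `"normal"`; selects the phred cutoff and is
#'   recorded in the output.
#' @param thresholds a [caller_thresholds()].
#' @return an allele tally data frame with columns `contig`, `pos`, `ref`,
#'   `alt`, `sample`, `alt_distinct_pairs`, `total_distinct_pairs`. Loci whose
#'   surviving pairs are all reference-supporting are kept with `alt = "."`
#'   and zero alternate pairs, so coverage is preserved for rule (iv).
#' @export
tally_observations <- function(obs, role = c("tumor", "normal"),
                               thresholds = caller_thresholds()) {
  role <- match.arg(role)
  cols <- c("contig", "pos", "ref", "allele", "is_paired", "is_quality_pass",
            "mapq", "min_phred", "fragment_id")
  if (nrow(obs) == 0) {
    return(empty_tally(role))
  }
  if (!all(cols %in% names(obs))) {
    fail_field("obs", paste("requires columns", paste(cols, collapse = ", ")))
  }
  cutoff <- if (role == "tumor") thresholds$tumor_phred_min else thresholds$normal_phred_min
  keep <- obs$is_paired & obs$is_quality_pass &
    obs$mapq >= thresholds$min_mapq & obs$min_phred > cutoff
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0) return(empty_tally(role))
  # one observation per distinct fragment at each locus
  frag_key <- paste(obs$contig, obs$pos, obs$fragment_id, sep = "\x1f")
  obs <- obs[!duplicated(frag_key), , drop = FALSE]
  loc <- paste(obs$contig, obs$pos, sep = "\x1f")
  out <- do.call(rbind, lapply(split(obs, loc), function(d) {
    total <- nrow(d)
    alts <- sort(unique(d$allele[d$allele != d$ref]))
    if (length(alts) == 0) {
      data.frame(contig = d$contig[1], pos = d$pos[1], ref = d$ref[1],
                 alt = ".", sample = role, alt_distinct_pairs = 0L,
                 total_distinct_pairs = total, stringsAsFactors = FALSE)
    } else {
      data.frame(contig = d$contig[1], pos = d$pos[1], ref = d$ref[1],
                 alt = alts, sample = role,
                 alt_distinct_pairs = vapply(alts, function(a) sum(d$allele == a), integer(1)),
                 total_distinct_pairs = total, stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

empty_tally <- function(role) {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), sample = character(),
             alt_distinct_pairs = integer(), total_distinct_pairs = integer(),
             stringsAsFactors = FALSE)
}

#' Call somatic mutations from matched tumour/normal allele tallies
#'
#' A tumour candidate (a tally row with a non-reference allele) is accepted
#' only if all rules hold; a rejection records the first failing rule code,
#' with the fraction rule (ii) taking precedence over the absolute-count
#' rule (i) when both fail (a 1/100 candidate is reported as a 2%-rule
#' failure, not a count failure):
#'
#' * **i** — at least `min_alt_pairs` distinct read pairs carry the mutation;
#' * **ii** — the alternate distinct-pair fraction is at least
#'   `tumor_fraction_min` of total distinct pairs (the 2% rule);
#' * **iii** — the mismatched base is present in at most
#'   `normal_fraction_max` of the matched normal's distinct pairs;
#' * **iv** — the position is covered (total distinct pairs > 0) in both
#'   tumour and normal;
#' * **germline** — `(locus, alt)` is not in the germline exclusion database;
#' * **blacklist** — optional site blacklist (stand-in for the manual visual
#'   inspection step of panel pipelines).
#'
#' Fractional abundance is 100 x alternate/total in the tumour, retained at
#' full precision in the `fractional_abundance` column (round with
#' [fractional_abundance()] / [round_half_up()] for reporting).
#'
#' @param tumor,normal allele tally data frames as from
#'   [tally_observations()] (or [read_tally_tsv()]). If both have exactly one
#'   row, they must refer to the same locus and alternate allele.
#' @param germline optional [germline_db()] (or data frame accepted by it).
#' @param thresholds a [caller_thresholds()].
#' @param blacklist optional data frame of sites (`contig`, `pos`) to reject.
#' @return data frame of calls: locus and allele columns, tumour/normal
#'   counts, `fractional_abundance` (percent), `status`
#'   (`"accepted"`/`"rejected"`) and `rule` (`NA` or the failing rule code).
#' @export
call_somatic <- function(tumor, normal, germline = NULL,
                         thresholds = caller_thresholds(), blacklist = NULL) {
  if (!is.null(germline) && !inherits(germline, "germline_db")) {
    germline <- germline_db(germline)
  }
  cand <- tumor[tumor$alt != ".", , drop = FALSE]
  if (nrow(tumor) == 1 && nrow(normal) == 1 &&
      (tumor$contig != normal$contig || tumor$pos != normal$pos)) {
    stop("tumor and normal tallies refer to different loci", call. = FALSE)
  }
  n_loc <- paste(normal$contig, normal$pos, sep = "\x1f")
  n_var <- paste(normal$contig, normal$pos, normal$alt, sep = "\x1f")
  bl <- if (!is.null(blacklist)) paste(blacklist$contig, blacklist$pos, sep = "\x1f") else character()
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, ]
    key_loc <- paste(r$contig, r$pos, sep = "\x1f")
    key_var <- paste(r$contig, r$pos, r$alt, sep = "\x1f")
    j <- match(key_var, n_var)
    n_total <- if (!is.na(j)) {
      normal$total_distinct_pairs[j]
    } else {
      jl <- match(key_loc, n_loc)
      if (!is.na(jl)) normal$total_distinct_pairs[jl] else 0L
    }
    n_alt <- if (!is.na(j)) normal$alt_distinct_pairs[j] else 0L
    t_frac <- if (r$total_distinct_pairs > 0) {
      r$alt_distinct_pairs / r$total_distinct_pairs
    } else 0
    n_frac <- if (n_total > 0) n_alt / n_total else 0
    rule <- NA_character_
    if (t_frac < thresholds$tumor_fraction_min) {
      rule <- "ii"
    } else if (r$alt_distinct_pairs < thresholds$min_alt_pairs) {
      rule <- "i"
    } else if (n_frac > thresholds$normal_fraction_max) {
      rule <- "iii"
    } else if (r$total_distinct_pairs == 0 || n_total == 0) {
      rule <- "iv"
    } else if (!is.null(germline) &&
               variant_key(r$contig, r$pos, r$ref, r$alt) %in% germline$keys) {
      rule <- "germline"
    } else if (key_loc %in% bl) {
      rule <- "blacklist"
    }
    data.frame(contig = r$contig, pos = r$pos, ref = r$ref, alt = r$alt,
               alt_distinct_pairs = r$alt_distinct_pairs,
               total_distinct_pairs = r$total_distinct_pairs,
               normal_alt_pairs = n_alt, normal_total_pairs = n_total,
               fractional_abundance = 100 * t_frac,
               status = if (is.na(rule)) "accepted" else "rejected",
               rule = rule, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), alt_distinct_pairs = integer(),
               total_distinct_pairs = integer(), normal_alt_pairs = integer(),
               normal_total_pairs = integer(), fractional_abundance = numeric(),
               status = character(), rule = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate accepted calls with their protein-coding consequence
#'
#' SNVs inside a CDS are classified by codon substitution against the
#' reading frame (missense / nonsense / silent); indels by length modulo 3
#' (frameshift / inframe-indel); positions within 2 bases of an interior CDS
#' edge are splice; other positions inside the gene footprint are intronic.
#' Silent and intronic calls are demoted to rejections with rule code
#' `"consequence"`; positions outside every panel gene get rule code
#' `"off-target"`. Missense, nonsense, frameshift and splice calls (plus
#' inframe indels) remain accepted.
#'
#' @param calls data frame from [call_somatic()].
#' @param model a [gene_model()].
#' @return `calls` with `gene` and `consequence` columns added and statuses
#'   updated.
#' @export
annotate_consequence <- function(calls, model) {
  if (!inherits(model, "gene_model")) fail_field("model", "must be a gene_model")
  calls$gene <- NA_character_
  calls$consequence <- NA_character_
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] != "accepted") next
    cl <- classify_variant(model, calls$contig[i], calls$pos[i],
                           calls$ref[i], calls$alt[i])
    calls$gene[i] <- cl$gene
    if (cl$region == "off-target") {
      calls$status[i] <- "rejected"
      calls$rule[i] <- "off-target"
    } else {
      calls$consequence[i] <- cl$class
      if (cl$class %in% c("silent", "intronic")) {
        calls$status[i] <- "rejected"
        calls$rule[i] <- "consequence"
      }
    }
  }
  calls
}

#' Fractional abundance of an allele tally, as reported
#'
#' 100 x alternate / total distinct read pairs, rounded half-up to one
#' decimal for reporting (full precision is carried in call tables).
#'
#' @param tally one-row allele tally (or any list with `alt_distinct_pairs`
#'   and `total_distinct_pairs`), or two numbers `alt` and `total` given as
#'   `tally` and `total`.
#' @param total optional; when given, `tally` is taken as the alternate count.
#' @return percent, one decimal.
#' @examples
#' fractional_abundance(13, 100) # 13.0
#' fractional_abundance(7, 33)   # 21.2
#' @export
fractional_abundance <- function(tally, total = NULL) {
  if (is.null(total)) {
    alt <- tally$alt_distinct_pairs
    total <- tally$total_distinct_pairs
  } else {
    alt <- tally
  }
  if (any(total == 0)) stop("fractional abundance undefined for zero total pairs", call. = FALSE)
  round_half_up(100 * alt / total, 1)
}

#' Germline exclusion database
#'
#' Set of known germline `(locus, alt)` records (e.g. common dbSNP variants)
#' excluded from somatic candidates.
#'
#' @param records data frame with columns `contig`, `pos`, `ref`, `alt`.
#' @return a `germline_db` object.
#' @seealso [read_germline()] for VCF/TSV input.
#' @export
germline_db <- function(records) {
  req <- c("contig", "pos", "ref", "alt")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    fail_field("records", paste("data frame with columns", paste(req, collapse = ", ")))
  }
  keys <- variant_key(records$contig, records$pos, records$ref, records$alt)
  if (anyDuplicated(keys)) fail_field("records", "duplicate (locus, alt) keys")
  structure(list(records = records, keys = keys), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("germline_db: %d variant(s)\n", length(x$keys)))
  invisible(x)
}
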