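#' Read and write the allele-tally TSV dialect
#'
#' Tab-separated, UTF-8, header required, columns `contig`, `pos`, `ref`,
#' `alt`, `sample`, `alt_distinct_pairs`, `total_distinct_pairs`. A `.` in
#' `alt` marks a covered locus with no alternate observations.
#'
#' @param path file path.
#' @return data frame in tally form.
#' @export
read_tally_tsv <- function(path) {
  req <- c("contig", "pos", "ref", "alt", "sample",
           "alt_distinct_pairs", "total_distinct_pairs")
  header <- names(utils::read.delim(path, nrows = 0))
  if (!all(req %in% header)) {
    fail_field("path", paste("tally TSV requires columns", paste(req, collapse = ", ")))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(alt = "character", ref = "character"))
  if (any(d$alt_distinct_pairs > d$total_distinct_pairs)) {
    fail_field("path", "alt_distinct_pairs exceeds total_distinct_pairs")
  }
  d
}

#' @rdname read_tally_tsv
#' @param tally tally data frame.
#' @export
write_tally_tsv <- function(tally, path) {
  utils::write.table(tally, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write droplet-count TSVs
#'
#' Columns `well`, `mutation_id`, `droplets_total`, `mutant_positive`,
#' `wildtype_positive`, `droplet_volume_nl` (an optional `compartment`
#' column is preserved for [ddpcr_concordance()]).
#'
#' @param path file path.
#' @return droplet-count data frame.
#' @export
read_droplet_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("well", "mutation_id", "droplets_total", "mutant_positive",
           "wildtype_positive", "droplet_volume_nl")
  if (!all(req %in% names(d))) {
    fail_field("path", paste("droplet TSV requires columns", paste(req, collapse = ", ")))
  }
  bad <- d$mutant_positive > d$droplets_total | d$wildtype_positive > d$droplets_total |
    d$mutant_positive < 0 | d$wildtype_positive < 0 | d$droplet_volume_nl <= 0
  if (any(bad)) fail_field("path", "droplet counts out of range")
  d
}

#' @rdname read_droplet_tsv
#' @param counts droplet-count data frame.
#' @export
write_droplet_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write presence matrices as 0/1 TSVs
#'
#' Zones as rows (first column `zone`), mutations as columns.
#'
#' @param path file path.
#' @param lesion lesion identifier for the constructed matrix.
#' @return a [mutation_zone_matrix()].
#' @export
read_matrix_tsv <- function(path, lesion = "lesion") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "zone") fail_field("path", "first column must be `zone`")
  m <- as.matrix(d[, -1, drop = FALSE]) == 1
  mutation_zone_matrix(d$zone, colnames(d)[-1], m, lesion)
}

#' @rdname read_matrix_tsv
#' @param matrix a [mutation_zone_matrix()].
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "mutation_zone_matrix"))
  d <- data.frame(zone = matrix$zones, 1 * matrix$mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a dendrogram to a Newick file, and dump it as JSON
#'
#' @param dendro a `clone_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  writeLines(to_newick(dendro), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_dendrogram_json <- function(dendro, path) {
  stopifnot(inherits(dendro, "clone_dendrogram"))
  obj <- list(lesion = dendro$lesion, root = dendro$root,
              nodes = lapply(stats::setNames(dendro$nodes, dendro$nodes), function(id) {
                list(zones = dendro$zones[[id]], mutations = dendro$sets[[id]],
                     parent = if (is.na(dendro$parent[[id]])) NULL else dendro$parent[[id]],
                     gained = dendro$gains[[id]])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a germline exclusion database from TSV or VCF
#'
#' TSV: four columns `contig`, `pos`, `ref`, `alt`. VCF: parsed with
#' `vcfR::read.vcfR()`; multi-allelic records are split.
#'
#' @param path `.vcf` or TSV file.
#' @return a [germline_db()].
#' @export
read_germline <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (!is.matrix(fx)) fx <- t(fx)  # single-record VCFs drop to a vector
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    rows <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
    }))
    germline_db(rows)
  } else {
    germline_db(utils::read.delim(path, stringsAsFactors = FALSE))
  }
}

#' Write somatic calls as VCF v4.2 (plus a rejected-records TSV)
#'
#' Accepted calls become VCF records with INFO keys `FA` (fractional
#' abundance, percent, one decimal), `GENE` and `CSQ` (consequence) when
#' annotated, and `DP`/`AO` depth counts. Rejected candidates go to a
#' parallel TSV (`<path>.rejected.tsv`) carrying the `RULE` code. Indel
#' alleles in the internal `-` dialect are re-anchored on the preceding
#' reference base when `model` provides sequence, otherwise written
#' symbolically (`<DEL>`/`<INS>`).
#'
#' @param calls call data frame from [call_somatic()] (annotated or not).
#' @param path output VCF path.
#' @param model optional [gene_model()] supplying reference sequence for
#'   indel anchoring.
#' @param sample_id sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, model = NULL, sample_id = "TUMOR") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=clonarch %s", as.character(utils::packageVersion("clonarch"))),
           sprintf("##sample=%s", sample_id),
           "##INFO=<ID=FA,Number=1,Type=Float,Description=\"Fractional abundance of alternate allele, percent\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total distinct read pairs\">",
           "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate distinct read pairs\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Predicted consequence\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  body <- vapply(seq_len(nrow(acc)), function(i) {
    r <- acc[i, ]
    pos <- r$pos
    ref <- r$ref
    alt <- r$alt
    if (ref == "-" || alt == "-") {
      anchor <- if (!is.null(model) && r$contig %in% names(model$reference) && pos > 1) {
        substr(model$reference[[r$contig]], pos - 1, pos - 1)
      } else ""
      if (nzchar(anchor)) {
        pos <- pos - 1
        if (alt == "-") { alt <- anchor; ref <- paste0(anchor, ref) }
        else { ref <- anchor; alt <- paste0(anchor, alt) }
      } else {
        if (alt == "-") alt <- "<DEL>" else { alt <- "<INS>"; ref <- "N" }
      }
    }
    info <- sprintf("FA=%.1f;DP=%d;AO=%d", round_half_up(r$fractional_abundance, 1),
                    r$total_distinct_pairs, r$alt_distinct_pairs)
    if ("gene" %in% names(r) && !is.na(r$gene)) info <- paste0(info, ";GENE=", r$gene)
    if ("consequence" %in% names(r) && !is.na(r$consequence)) {
      info <- paste0(info, ";CSQ=", r$consequence)
    }
    paste(r$contig, pos, ".", ref, alt, ".", "PASS", info, sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  rej <- calls[calls$status == "rejected", , drop = FALSE]
  utils::write.table(rej, paste0(path, ".rejected.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write per-gene coverage TSVs
#'
#' Columns `sample`, `gene`, `avg_depth`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_coverage_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "gene", "avg_depth")
  if (!all(req %in% names(d))) {
    fail_field("path", paste("coverage TSV requires columns", paste(req, collapse = ", ")))
  }
  d
}

#' Write simulation ground truth as JSON
#'
#' @param truth a [ground_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(mutations = lapply(stats::setNames(truth$mutations, truth$mutations),
                                 function(m) {
    list(zones = truth$zone_presence[[m]],
         cellular_fraction = as.list(truth$cellular_fraction[m, ]),
         fluid_fraction_pct = truth$fluid_fraction_pct[[m]])
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
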