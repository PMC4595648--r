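#' Build a gene-panel model
#'
#' A gene model holds, per panel gene, its contig, strand and CDS intervals
#' (1-based, closed), together with the reference sequence of each contig.
#' It is the annotation source for [annotate_consequence()]: coding positions,
#' reading frames and codons are all derived from it.
#'
#' @param cds data frame with columns `gene`, `contig`, `strand` (`"+"` or
#'   `"-"`), `start`, `end` (1-based, closed). Intervals of one gene must not
#'   overlap; they are sorted internally.
#' @param reference named character vector (or `Biostrings::DNAStringSet`)
#'   of contig sequences covering every CDS interval.
#' @return an object of class `gene_model` with elements `cds` (the sorted
#'   interval table), `reference`, and per-gene coding maps (vector of genomic
#'   positions in coding order plus the coding-strand sequence).
#' @seealso [read_gene_model()] for BED12 input, [annotate_consequence()].
#' @export
gene_model <- function(cds, reference) {
  req <- c("gene", "contig", "strand", "start", "end")
  if (!is.data.frame(cds) || !all(req %in% names(cds))) {
    fail_field("cds", paste("data frame with columns", paste(req, collapse = ", ")))
  }
  if (!all(cds$strand %in% c("+", "-"))) fail_field("strand", "must be '+' or '-'")
  if (!all(cds$start >= 1) || !all(cds$end >= cds$start)) {
    fail_field("cds", "intervals must satisfy 1 <= start <= end")
  }
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    fail_field("reference", "must be a named vector of contig sequences")
  }
  cds <- cds[order(cds$gene, cds$contig, cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  for (g in unique(cds$gene)) {
    iv <- cds[cds$gene == g, , drop = FALSE]
    if (length(unique(iv$contig)) > 1L || length(unique(iv$strand)) > 1L) {
      fail_field("cds", sprintf("gene %s spans multiple contigs or strands", g))
    }
    if (nrow(iv) > 1L && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      fail_field("cds", sprintf("overlapping CDS intervals in gene %s", g))
    }
    if (!iv$contig[1] %in% names(reference)) {
      fail_field("reference", sprintf("no sequence for contig %s", iv$contig[1]))
    }
    if (max(iv$end) > nchar(reference[[iv$contig[1]]])) {
      fail_field("reference", sprintf("contig %s shorter than CDS of %s", iv$contig[1], g))
    }
  }
  maps <- lapply(split(cds, cds$gene), function(iv) {
    genomic <- unlist(mapply(seq.int, iv$start, iv$end, SIMPLIFY = FALSE))
    bases <- strsplit(reference[[iv$contig[1]]], "")[[1]][genomic]
    if (iv$strand[1] == "-") {
      genomic <- rev(genomic)
      bases <- chartr("ACGTacgt", "TGCAtgca", rev(bases))
    }
    list(contig = iv$contig[1], strand = iv$strand[1],
         genomic = genomic, coding_seq = toupper(paste(bases, collapse = "")))
  })
  structure(list(cds = cds, reference = reference, maps = maps),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d gene(s), %d CDS interval(s) on %d contig(s)\n",
              length(x$maps), nrow(x$cds), length(unique(x$cds$contig))))
  invisible(x)
}

#' Read a gene-panel model from a BED12 or TSV interval file
#'
#' BED12 files are parsed with `rtracklayer::import()`; each record's blocks
#' become the CDS intervals of one gene (the `name` field). Alternatively a
#' plain TSV with columns `gene`, `contig`, `strand`, `start`, `end` (1-based,
#' closed) is accepted.
#'
#' @param path BED12 (`.bed`) or TSV file.
#' @param reference named character vector or `DNAStringSet` of contig
#'   sequences, or a FASTA path (read with `Biostrings::readDNAStringSet()`).
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path, reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading BED12 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "BED")
    df <- as.data.frame(gr)
    rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      # blocks are 1-based ranges relative to the record start
      b <- as.data.frame(gr$blocks[[i]])
      data.frame(gene = df$name[i],
                 contig = as.character(df$seqnames[i]),
                 strand = as.character(df$strand[i]),
                 start = df$start[i] + b$start - 1L,
                 end = df$start[i] + b$end - 1L)
    }))
    rows$strand[!rows$strand %in% c("+", "-")] <- "+"
    gene_model(rows, reference)
  } else {
    gene_model(utils::read.delim(path, stringsAsFactors = FALSE), reference)
  }
}

# Locate a position relative to the panel. Returns a list with:
#   region: "cds" | "splice" | "intronic" | "off-target"
#   gene:   gene symbol (NA when off-target)
#   coding_pos: 1-based position in the coding sequence (cds only)
locate_position <- function(model, contig, pos, splice_window = 2L) {
  hit_splice <- NULL
  hit_intron <- NULL
  for (g in names(model$maps)) {
    m <- model$maps[[g]]
    if (m$contig != contig) next
    iv <- model$cds[model$cds$gene == g, , drop = FALSE]
    span <- c(min(iv$start), max(iv$end))
    cp <- match(pos, m$genomic)
    if (!is.na(cp)) {
      return(list(region = "cds", gene = g, coding_pos = cp))
    }
    # interior CDS edges: every interval boundary except the two outermost
    edges_lo <- setdiff(iv$start, span[1])   # intron ends just before these
    edges_hi <- setdiff(iv$end, span[2])     # introns begin just after these
    near <- any(pos >= edges_lo - splice_window & pos < edges_lo) ||
      any(pos > edges_hi & pos <= edges_hi + splice_window)
    if (near && is.null(hit_splice)) hit_splice <- g
    if (pos >= span[1] && pos <= span[2] && is.null(hit_intron)) hit_intron <- g
  }
  if (!is.null(hit_splice)) return(list(region = "splice", gene = hit_splice, coding_pos = NA))
  if (!is.null(hit_intron)) return(list(region = "intronic", gene = hit_intron, coding_pos = NA))
  list(region = "off-target", gene = NA_character_, coding_pos = NA)
}

# Classify a single variant against the model. Alleles use the tally dialect:
# SNVs are single bases; deletions have alt == "-" (ref = deleted span);
# insertions have ref == "-" (alt = inserted bases).
classify_variant <- function(model, contig, pos, ref, alt) {
  loc <- locate_position(model, contig, pos)
  if (loc$region == "off-target") return(list(class = NA_character_, gene = NA_character_,
                                              region = "off-target"))
  is_indel <- ref == "-" || alt == "-" || nchar(ref) != nchar(alt)
  cls <- if (loc$region == "splice") {
    "splice"
  } else if (loc$region == "intronic") {
    "intronic"
  } else if (is_indel) {
    len <- abs(nchar(gsub("-", "", alt)) - nchar(gsub("-", "", ref)))
    if (len %% 3L != 0L) "frameshift" else "inframe-indel"
  } else {
    classify_snv_codon(model, loc$gene, loc$coding_pos, ref, alt)
  }
  list(class = cls, gene = loc$gene, region = loc$region)
}

classify_snv_codon <- function(model, gene, coding_pos, ref, alt) {
  m <- model$maps[[gene]]
  if (m$strand == "-") {
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  codon_i <- (coding_pos - 1L) %/% 3L
  within <- (coding_pos - 1L) %% 3L + 1L
  codon <- substr(m$coding_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("missense")  # trailing partial codon: be lenient
  if (substr(codon, within, within) != ref) {
    warning(sprintf("reference allele mismatch for %s coding position %d", gene, coding_pos))
  }
  mutated <- codon
  substr(mutated, within, within) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mutated])
  if (is.na(aa_alt) || is.na(aa_ref)) return("missense")
  if (aa_alt == aa_ref) "silent" else if (aa_alt == "*") "nonsense" else "missense"
}
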