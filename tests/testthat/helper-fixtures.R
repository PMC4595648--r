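# Hand-built two-gene panel with known codon structure:
#   GA (+ strand, ctg1:11-22): ATG GGT AAA TAA
#   GB (- strand, CDS ctg1:31-36 + 45-50): coding ATG CCC TAA TAA
# GB's intron spans 37-44: splice window 37,38 and 43,44; intronic 39-42.
tiny_reference <- function() {
  s <- rep("C", 60)
  s[11:22] <- strsplit("ATGGGTAAATAA", "")[[1]]
  s[31:36] <- strsplit("TTATTA", "")[[1]]
  s[45:50] <- strsplit("GGGCAT", "")[[1]]
  stats::setNames(paste(s, collapse = ""), "ctg1")
}

tiny_model <- function() {
  gene_model(data.frame(gene = c("GA", "GB", "GB"),
                        contig = "ctg1",
                        strand = c("+", "-", "-"),
                        start = c(11, 31, 45),
                        end = c(22, 36, 50)),
             tiny_reference())
}

# One-row allele tally in the TSV dialect.
make_tally <- function(alt_pairs, total_pairs, sample = "tumor",
                       contig = "c1", pos = 100, ref = "A", alt = "G") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, sample = sample,
             alt_distinct_pairs = alt_pairs, total_distinct_pairs = total_pairs,
             stringsAsFactors = FALSE)
}

# One read-pair observation row.
make_obs <- function(allele, fragment_id, ref = "A", pos = 100,
                     is_paired = TRUE, is_quality_pass = TRUE,
                     mapq = 60, min_phred = 38) {
  data.frame(contig = "c1", pos = pos, ref = ref, allele = allele,
             is_paired = is_paired, is_quality_pass = is_quality_pass,
             mapq = mapq, min_phred = min_phred, fragment_id = fragment_id,
             stringsAsFactors = FALSE)
}

# Presence matrix from a named list zone -> character vector of mutations.
matrix_from_sets <- function(sets, lesion = "lesion") {
  zones <- names(sets)
  muts <- unique(unlist(sets, use.names = FALSE))
  if (length(muts) == 0) muts <- character()
  mat <- matrix(FALSE, length(zones), length(muts),
                dimnames = list(zones, muts))
  for (z in zones) mat[z, sets[[z]]] <- TRUE
  mutation_zone_matrix(zones, muts, mat, lesion)
}
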