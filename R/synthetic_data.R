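#' Configuration for the multi-zone clonal-evolution simulator
#'
#' Defaults emulate the study conditions of multi-region targeted panel
#' sequencing of early lung neoplasia: four histologic zones per lesion,
#' tumour purity 0.6 per zone (microdissection to > 60% neoplastic cells),
#' mean distinct read-pair depth 400x (panel depths of roughly 400-485x),
#' per-base error 0.1%, and ddPCR partitioning of 10,000 template copies
#' into ~20,000 droplets of ~1 nl.
#'
#' @param n_zones number of zones sampled from the lesion (>= 1).
#' @param panel a [gene_model()]; defaults to a seeded synthetic panel
#'   ([synthetic_panel()]) built from `random_seed`.
#' @param n_truncal,n_branch,n_private mutation counts assigned to the root
#'   branch, internal branches, and leaf branches respectively.
#' @param tumor_purity per-zone tumour cell fraction in `[0, 1]` (scalar or
#'   length `n_zones`).
#' @param mean_depth mean distinct read pairs per locus.
#' @param per_base_error per-base sequencing error probability.
#' @param droplet_count number of ddPCR droplets formed per well.
#' @param droplet_volume_nl droplet volume in nanolitres.
#' @param template_copies total template copies loaded per ddPCR well.
#' @param random_seed mandatory integer master seed; every random draw in the
#'   simulator is derived from it (no implicit entropy).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_zones = 4, panel = NULL,
                              n_truncal = 3, n_branch = 4, n_private = 5,
                              tumor_purity = 0.6, mean_depth = 400,
                              per_base_error = 0.001,
                              droplet_count = 20000, droplet_volume_nl = 1,
                              template_copies = 10000, random_seed) {
  if (missing(random_seed) || !is_count(random_seed)) {
    fail_field("random_seed", "a non-negative integer seed is mandatory")
  }
  if (!is_count(n_zones, min = 1)) fail_field("n_zones", "must be a positive integer")
  for (f in c("n_truncal", "n_branch", "n_private")) {
    if (!is_count(get(f))) fail_field(f, "must be a non-negative count")
  }
  if (!all(vapply(tumor_purity, is_prob, logical(1)))) {
    fail_field("tumor_purity", "must be in [0, 1]")
  }
  if (!length(tumor_purity) %in% c(1L, n_zones)) {
    fail_field("tumor_purity", "must be scalar or one value per zone")
  }
  if (!is_count(mean_depth, min = 1)) fail_field("mean_depth", "must be >= 1")
  if (!is_prob(per_base_error)) fail_field("per_base_error", "must be in [0, 1]")
  if (!is_count(droplet_count)) fail_field("droplet_count", "must be a non-negative count")
  if (!is.numeric(droplet_volume_nl) || droplet_volume_nl <= 0) {
    fail_field("droplet_volume_nl", "must be > 0")
  }
  if (!is_count(template_copies)) fail_field("template_copies", "must be a non-negative count")
  if (is.null(panel)) panel <- synthetic_panel(seed = random_seed)
  structure(list(n_zones = as.integer(n_zones), panel = panel,
                 n_truncal = as.integer(n_truncal),
                 n_branch = as.integer(n_branch),
                 n_private = as.integer(n_private),
                 tumor_purity = rep(tumor_purity, length.out = n_zones),
                 mean_depth = mean_depth, per_base_error = per_base_error,
                 droplet_count = as.integer(droplet_count),
                 droplet_volume_nl = droplet_volume_nl,
                 template_copies = as.integer(template_copies),
                 random_seed = as.integer(random_seed)),
            class = "simulation_config")
}

#' Seeded synthetic gene panel
#'
#' A small panel of single-exon and multi-exon genes with random reference
#' sequence, used as the default [gene_model()] for simulations. Synthetic:
#' it resembles a targeted cancer-driver panel in shape (CDS-only capture)
#' but its sequences and coordinates carry no biological meaning.
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return a [gene_model()].
#' @export
synthetic_panel <- function(n_genes = 8, seed = 1) {
  with_seed(derive_seed(seed, "panel"), {
    contig <- "panel1"
    cursor <- 1000L
    rows <- list()
    for (i in seq_len(n_genes)) {
      n_exon <- sample(1:3, 1)
      strand <- sample(c("+", "-"), 1)
      starts <- integer(n_exon); ends <- integer(n_exon)
      for (e in seq_len(n_exon)) {
        len <- 3L * sample(20:60, 1)     # keep total CDS a codon multiple
        starts[e] <- cursor
        ends[e] <- cursor + len - 1L
        cursor <- ends[e] + sample(40:120, 1)  # intron / intergenic gap
      }
      rows[[i]] <- data.frame(gene = sprintf("G%02d", i), contig = contig,
                              strand = strand, start = starts, end = ends)
      cursor <- cursor + 200L
    }
    cds <- do.call(rbind, rows)
    seq_len_total <- max(cds$end) + 500L
    reference <- stats::setNames(
      paste(sample(c("A", "C", "G", "T"), seq_len_total, replace = TRUE), collapse = ""),
      contig)
    gene_model(cds, reference)
  })
}

#' Simulate a clone tree with zone compositions
#'
#' Generates one truncal (root) clone plus subclones: one leaf clone per
#' zone and internal clones from a seeded recursive bipartition of the zone
#' set. Truncal mutations sit on the root branch, branch mutations on
#' internal branches (shared by the zones below them), private mutations on
#' leaf branches. Each zone's cell population is its leaf clone at the
#' configured tumour purity, the remainder normal cells.
#'
#' @param config a [simulation_config()].
#' @return a `clone_tree` list: `nodes`, `parent` (child -> parent map, root
#'   maps to `NA`), `mutations_on_branch`, `zone_composition`
#'   (zone -> clone mixing fractions; the normal-cell fraction is the
#'   complement), and `zone_clone` (zone -> its leaf clone).
#' @export
simulate_clone_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  z <- config$n_zones
  zones <- sprintf("Z%d", seq_len(z))
  nodes <- "C0"
  parent <- c(C0 = NA_character_)
  zone_clone <- stats::setNames(rep("C0", z), zones)
  counter <- new.env()
  counter$i <- 0L
  new_clone <- function(p) {
    counter$i <- counter$i + 1L
    id <- sprintf("C%d", counter$i)
    nodes <<- c(nodes, id)
    parent[id] <<- p
    id
  }
  internal_edges <- character()
  leaf_edges <- character()
  with_seed(derive_seed(config$random_seed, "tree"), {
    if (z == 1L) {
      zone_clone[zones] <- "C0"
    } else {
      split_zones <- function(members, parent_clone) {
        if (length(members) == 1L) {
          cl <- new_clone(parent_clone)
          leaf_edges <<- c(leaf_edges, cl)
          zone_clone[members] <<- cl
          return(invisible(NULL))
        }
        # random bipartition into two non-empty groups
        k <- sample(seq_len(length(members) - 1L), 1)
        pick <- sample(members, k)
        for (grp in list(pick, setdiff(members, pick))) {
          if (length(grp) == 1L) {
            split_zones(grp, parent_clone)
          } else {
            cl <- new_clone(parent_clone)
            internal_edges <<- c(internal_edges, cl)
            split_zones(grp, cl)
          }
        }
      }
      split_zones(zones, "C0")
    }
    muts <- list()
    mut_id <- function(kind, i) sprintf("%s%d", kind, i)
    assign_muts <- function(n, kind, branches) {
      if (n == 0L || length(branches) == 0L) return(character())
      ids <- vapply(seq_len(n), function(i) mut_id(kind, i), character(1))
      tgt <- branches[(seq_len(n) - 1L) %% length(branches) + 1L]
      for (i in seq_len(n)) muts[[tgt[i]]] <<- c(muts[[tgt[i]]], ids[i])
      ids
    }
    assign_muts(config$n_truncal, "T", "C0")
    # with < 3 zones no internal branch exists; shared mutations then fall
    # through to leaf branches (effectively private)
    branch_target <- if (length(internal_edges)) internal_edges else leaf_edges
    assign_muts(config$n_branch, "B", branch_target)
    # private mutations spread over leaf branches; round-robin keeps the
    # per-zone private load balanced and deterministic
    if (config$n_private > 0L && length(leaf_edges)) {
      assign_muts(config$n_private, "P", sample(leaf_edges))
    } else if (config$n_private > 0L) {
      assign_muts(config$n_private, "P", "C0")
    }
    composition <- stats::setNames(lapply(seq_len(z), function(i) {
      stats::setNames(config$tumor_purity[i], zone_clone[zones[i]])
    }), zones)
    structure(list(nodes = nodes, parent = parent,
                   mutations_on_branch = muts,
                   zone_composition = composition,
                   zone_clone = zone_clone),
              class = "clone_tree")
  })
}

#' @export
print.clone_tree <- function(x, ...) {
  n_mut <- length(unlist(x$mutations_on_branch))
  cat(sprintf("clone_tree: %d clone(s), %d zone(s), %d mutation(s)\n",
              length(x$nodes), length(x$zone_composition), n_mut))
  invisible(x)
}

# Clones on the path from the root down to `clone` (inclusive).
clone_path <- function(tree, clone) {
  path <- clone
  while (!is.na(tree$parent[[clone]])) {
    clone <- tree$parent[[clone]]
    path <- c(clone, path)
  }
  path
}

#' Ground truth for a simulated clone tree
#'
#' Per mutation: the set of zones whose clone lineage carries it, its true
#' cellular fraction per zone (fraction of tumour cells carrying it; 1 on
#' the lineage under the single-clone-per-zone composition, else 0), and a
#' true fluid fractional abundance in percent drawn log-uniformly in
#' `[0.03, 1]`%, bracketing mutant circulating-DNA fractions observed in
#' plasma and sputum.
#'
#' @param tree a [simulate_clone_tree()] result.
#' @param config the matching [simulation_config()].
#' @return a `ground_truth` list: `mutations`, `zone_presence` (mutation ->
#'   zone character vector), `cellular_fraction` (mutation x zone matrix) and
#'   `fluid_fraction_pct` (named numeric).
#' @export
ground_truth <- function(tree, config) {
  stopifnot(inherits(tree, "clone_tree"))
  zones <- names(tree$zone_composition)
  muts <- unlist(tree$mutations_on_branch, use.names = FALSE)
  branch_of <- stats::setNames(
    rep(names(tree$mutations_on_branch),
        vapply(tree$mutations_on_branch, length, integer(1))),
    muts)
  cf <- matrix(0, nrow = length(muts), ncol = length(zones),
               dimnames = list(muts, zones))
  for (zn in zones) {
    path <- clone_path(tree, tree$zone_clone[[zn]])
    on_path <- muts[branch_of[muts] %in% path]
    cf[on_path, zn] <- 1
  }
  presence <- lapply(stats::setNames(muts, muts), function(m) zones[cf[m, ] > 0])
  fluid <- with_seed(derive_seed(config$random_seed, "fluid"), {
    stats::setNames(10^stats::runif(length(muts), log10(0.03), log10(1)), muts)
  })
  structure(list(mutations = muts, zone_presence = presence,
                 cellular_fraction = cf, fluid_fraction_pct = fluid),
            class = "ground_truth")
}

# Place each mutation at a distinct coding position of the synthetic panel,
# choosing an alternate allele that changes the encoded amino acid so that
# consequence filtering keeps true somatic calls.
place_mutations <- function(truth, config) {
  model <- config$panel
  with_seed(derive_seed(config$random_seed, "placement"), {
    genes <- names(model$maps)
    out <- list()
    used <- character()
    for (m in truth$mutations) {
      repeat {
        g <- sample(genes, 1)
        map <- model$maps[[g]]
        cp <- sample(seq_along(map$genomic), 1)
        pos <- map$genomic[cp]
        key <- locus_key(map$contig, pos)
        if (key %in% used) next
        ref <- substr(model$reference[[map$contig]], pos, pos)
        # try alternates until one is non-silent
        alts <- sample(setdiff(c("A", "C", "G", "T"), ref))
        picked <- NA_character_
        for (alt in alts) {
          cls <- classify_variant(model, map$contig, pos, ref, alt)$class
          if (!identical(cls, "silent")) { picked <- alt; break }
        }
        if (is.na(picked)) next
        used <- c(used, key)
        out[[m]] <- data.frame(mutation = m, gene = g, contig = map$contig,
                               pos = pos, ref = ref, alt = picked,
                               stringsAsFactors = FALSE)
        break
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate distinct read-pair allele tallies for a clone tree
#'
#' At each mutated locus the expected alternate distinct-pair fraction in a
#' zone is `purity x cellular_fraction x 0.5 + per_base_error` (heterozygous
#' single-copy model); the matched normal carries only error-driven
#' alternates. Total distinct pairs per locus are Poisson around
#' `mean_depth` (minimum 1) and alternate pairs binomial, with all draws in
#' seeded sub-streams keyed by (zone, locus) so enlarging a cohort never
#' perturbs existing draws.
#'
#' @param tree a [simulate_clone_tree()] result.
#' @param truth the matching [ground_truth()].
#' @param config the matching [simulation_config()].
#' @param loci optional mutation placement table (from an earlier call),
#'   otherwise placed afresh from the seed.
#' @return list with `tumor` (named list zone -> tally data frame in the
#'   tally TSV dialect), `normal` (one tally data frame), and `loci` (the
#'   placement table joining mutation ids to panel coordinates).
#' @export
simulate_tallies <- function(tree, truth, config, loci = NULL) {
  stopifnot(inherits(tree, "clone_tree"), inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  if (config$mean_depth < 1) fail_field("mean_depth", "must be >= 1")
  if (is.null(loci)) loci <- place_mutations(truth, config)
  zones <- names(tree$zone_composition)
  sample_tally <- function(role, zone = NULL) {
    rows <- lapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i, ]
      p <- if (identical(role, "normal")) {
        config$per_base_error
      } else {
        zi <- match(zone, zones)
        if (is.na(zi)) stop(sprintf("zone %s not in tree", zone), call. = FALSE)
        config$tumor_purity[zi] * truth$cellular_fraction[l$mutation, zone] * 0.5 +
          config$per_base_error
      }
      sub <- derive_seed(config$random_seed, "tally",
                         if (is.null(zone)) "normal" else zone, l$contig, l$pos)
      with_seed(sub, {
        total <- max(1L, stats::rpois(1, config$mean_depth))
        alt <- stats::rbinom(1, total, min(p, 1))
        data.frame(contig = l$contig, pos = l$pos, ref = l$ref, alt = l$alt,
                   sample = if (is.null(zone)) "normal" else zone,
                   alt_distinct_pairs = alt, total_distinct_pairs = total,
                   stringsAsFactors = FALSE)
      })
    })
    do.call(rbind, rows)
  }
  tumor <- stats::setNames(lapply(zones, function(zn) sample_tally("tumor", zn)), zones)
  normal <- sample_tally("normal")
  list(tumor = tumor, normal = normal, loci = loci)
}

#' Simulate paired tumour/normal tallies for independent SNV loci
#'
#' Building block for caller benchmarking: `n` unrelated true somatic SNVs
#' with given tumour alternate fractions, each locus an independent
#' Poisson-depth / binomial-count draw, matched normal driven by
#' `per_base_error` only.
#'
#' @param n number of loci.
#' @param alt_fraction tumour alternate fraction(s), recycled to length `n`.
#' @param mean_depth mean distinct read pairs per locus (tumour and normal).
#' @param per_base_error per-base error probability.
#' @param seed integer seed.
#' @return list of `tumor` and `normal` tally data frames (loci `S1..Sn` on
#'   contig `"sim"`, ref `"A"`, alt `"G"`).
#' @export
simulate_snv_tallies <- function(n, alt_fraction, mean_depth = 400,
                                 per_base_error = 0.001, seed) {
  if (missing(seed)) fail_field("seed", "a seed is mandatory")
  alt_fraction <- rep(alt_fraction, length.out = n)
  with_seed(derive_seed(seed, "snv_tallies"), {
    t_total <- pmax(1L, stats::rpois(n, mean_depth))
    n_total <- pmax(1L, stats::rpois(n, mean_depth))
    p <- pmin(alt_fraction + per_base_error * (1 - alt_fraction), 1)
    t_alt <- stats::rbinom(n, t_total, p)
    n_alt <- stats::rbinom(n, n_total, per_base_error)
    pos <- seq_len(n)
    list(tumor = data.frame(contig = "sim", pos = pos, ref = "A", alt = "G",
                            sample = "tumor", alt_distinct_pairs = t_alt,
                            total_distinct_pairs = t_total, stringsAsFactors = FALSE),
         normal = data.frame(contig = "sim", pos = pos, ref = "A", alt = "G",
                             sample = "normal", alt_distinct_pairs = n_alt,
                             total_distinct_pairs = n_total, stringsAsFactors = FALSE))
  })
}

#' Simulate one ddPCR well
#'
#' Mutant and wild-type template copies (split by `true_fraction_pct`) are
#' partitioned uniformly at random into `droplet_count` droplets; a droplet
#' is positive for a channel iff at least one template of that channel
#' landed in it.
#'
#' @param true_fraction_pct true mutant fractional abundance in percent.
#' @param config a [simulation_config()] (uses `template_copies`,
#'   `droplet_count`, `droplet_volume_nl`, `random_seed`).
#' @param well well identifier for the output row.
#' @param mutation_id mutation identifier for the output row.
#' @param seed optional override of the derived seed (used by [lod_series()]
#'   for replicate sub-streams).
#' @return one-row data frame: `well`, `mutation_id`, `droplets_total`,
#'   `mutant_positive`, `wildtype_positive`, `droplet_volume_nl`.
#' @export
simulate_droplets <- function(true_fraction_pct, config, well = "A01",
                              mutation_id = "mut", seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(true_fraction_pct) || true_fraction_pct < 0 || true_fraction_pct > 100) {
    fail_field("true_fraction_pct", "must be in [0, 100]")
  }
  if (config$droplet_count == 0L) fail_field("droplet_count", "must be positive")
  m <- round(config$template_copies * true_fraction_pct / 100)
  w <- config$template_copies - m
  if (is.null(seed)) seed <- derive_seed(config$random_seed, "droplets", well, mutation_id)
  with_seed(seed, {
    k_m <- length(unique(sample.int(config$droplet_count, m, replace = TRUE)))
    k_w <- length(unique(sample.int(config$droplet_count, w, replace = TRUE)))
    data.frame(well = well, mutation_id = mutation_id,
               droplets_total = config$droplet_count,
               mutant_positive = if (m == 0) 0L else k_m,
               wildtype_positive = if (w == 0) 0L else k_w,
               droplet_volume_nl = config$droplet_volume_nl,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full multi-zone cohort with ground truth
#'
#' Convenience wrapper: one clone tree, ground truth, tallies and (optional)
#' fluid droplet counts per lesion.
#'
#' @param n_lesions number of lesions (patients).
#' @param config a [simulation_config()]; per-lesion seeds are derived from
#'   its `random_seed`.
#' @param fluid if `TRUE`, also simulate one ddPCR well per mutation at its
#'   true fluid fraction.
#' @return named list of lesions, each with `tree`, `truth`, `tallies` and
#'   optionally `droplets`.
#' @export
simulate_cohort <- function(n_lesions, config, fluid = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  lesions <- sprintf("L%02d", seq_len(n_lesions))
  stats::setNames(lapply(seq_len(n_lesions), function(i) {
    cfg <- config
    cfg$random_seed <- derive_seed(config$random_seed, "lesion", lesions[i])
    tree <- simulate_clone_tree(cfg)
    truth <- ground_truth(tree, cfg)
    tallies <- simulate_tallies(tree, truth, cfg)
    res <- list(tree = tree, truth = truth, tallies = tallies)
    if (fluid) {
      res$droplets <- do.call(rbind, lapply(truth$mutations, function(m) {
        simulate_droplets(truth$fluid_fraction_pct[[m]], cfg,
                          well = sprintf("W%s", m), mutation_id = m)
      }))
    }
    res
  }), lesions)
}
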