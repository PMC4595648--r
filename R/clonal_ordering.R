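#' Construct a zones x mutations presence matrix
#'
#' @param zones ordered zone labels (no duplicates).
#' @param mutations ordered mutation identifiers (no duplicates).
#' @param mat logical matrix, zones as rows, mutations as columns.
#' @param lesion lesion identifier.
#' @return a `mutation_zone_matrix`.
#' @export
mutation_zone_matrix <- function(zones, mutations, mat, lesion = "lesion") {
  if (anyDuplicated(zones)) fail_field("zones", "duplicate zone labels")
  if (anyDuplicated(mutations)) fail_field("mutations", "duplicate mutation labels")
  mat <- as.matrix(mat)
  if (nrow(mat) != length(zones) || ncol(mat) != length(mutations)) {
    fail_field("mat", "dimensions must match zone and mutation label counts")
  }
  mode(mat) <- "logical"
  dimnames(mat) <- list(zones, mutations)
  structure(list(lesion = lesion, zones = zones, mutations = mutations, mat = mat),
            class = "mutation_zone_matrix")
}

#' @export
print.mutation_zone_matrix <- function(x, ...) {
  cat(sprintf("mutation_zone_matrix '%s': %d zone(s) x %d mutation(s)\n",
              x$lesion, length(x$zones), length(x$mutations)))
  print(x$mat)
  invisible(x)
}

#' Build a presence matrix from per-zone somatic calls
#'
#' Mutation identity is the `(gene, locus, ref, alt)` tuple, so the same
#' variant called in several zones yields a single matrix column. Only
#' accepted calls count; silent and intronic consequences are excluded
#' (synonymous and non-coding changes play no part in clonal ordering).
#'
#' @param calls_per_zone named list, zone label -> data frame of calls
#'   ([call_somatic()] / [annotate_consequence()] output).
#' @param lesion lesion identifier.
#' @return a [mutation_zone_matrix()].
#' @export
build_matrix <- function(calls_per_zone, lesion = "lesion") {
  if (length(calls_per_zone) < 1 || is.null(names(calls_per_zone))) {
    fail_field("calls_per_zone", "a named list with at least one zone is required")
  }
  zones <- names(calls_per_zone)
  keyed <- lapply(calls_per_zone, function(d) {
    if (nrow(d) == 0) return(character())
    keep <- if ("status" %in% names(d)) d$status == "accepted" else rep(TRUE, nrow(d))
    if ("consequence" %in% names(d)) {
      keep <- keep & (is.na(d$consequence) | !d$consequence %in% c("silent", "intronic"))
    }
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0) return(character())
    gene <- if ("gene" %in% names(d)) ifelse(is.na(d$gene), "", d$gene) else ""
    unique(paste(gene, d$contig, d$pos, d$ref, d$alt, sep = ":"))
  })
  mutations <- unique(unlist(keyed, use.names = FALSE))
  mat <- matrix(FALSE, nrow = length(zones), ncol = length(mutations),
                dimnames = list(zones, mutations))
  for (zn in zones) mat[zn, keyed[[zn]]] <- TRUE
  mutation_zone_matrix(zones, mutations, mat, lesion)
}

#' Infer a clonal-ancestry dendrogram from a presence matrix
#'
#' Containment ordering across lesion zones: a zone containing all
#' mutations observed in another zone is its ancestor (the candidate with
#' the largest mutation set being the closest ancestor); zones with equal
#' non-empty mutation sets merge into one clade node. Where no sequenced
#' zone qualifies, putative precursor nodes are inferred from the set of
#' alterations common to multiple zones, grouping the zones sharing the
#' largest common subsets first. The root carries the intersection of all
#' non-empty zone sets. Zones with no alterations attach as parallel
#' branches at the root by default; with `empty_as_ancestor = TRUE` they are
#' instead placed as the ancestor of all mutated zones.
#'
#' @param matrix a [mutation_zone_matrix()].
#' @param empty_as_ancestor treat mutation-free zones as ancestors rather
#'   than parallel branches.
#' @return a `clone_dendrogram`: `nodes` (ids), `zones` (id -> member zone
#'   labels), `sets` (id -> mutation set), `parent` (id -> parent id, root
#'   `NA`), `gains` (id -> mutations gained on the edge from its parent),
#'   `root` (root id).
#' @export
infer_ancestry <- function(matrix, empty_as_ancestor = FALSE) {
  stopifnot(inherits(matrix, "mutation_zone_matrix"))
  zones <- matrix$zones
  sets <- lapply(zones, function(z) sort(matrix$mutations[matrix$mat[z, ]]))
  names(sets) <- zones
  filled <- zones[lengths(sets) > 0]
  empty_zones <- setdiff(zones, filled)

  node_sets <- list()
  node_zones <- list()
  ids <- character()
  # zones with identical non-empty sets collapse into one clade node
  if (length(filled)) {
    sig <- vapply(sets[filled], paste, character(1), collapse = "\x1f")
    for (s in unique(sig)) {
      zs <- filled[sig == s]
      id <- paste(zs, collapse = "+")
      ids <- c(ids, id)
      node_sets[[id]] <- sets[[zs[1]]]
      node_zones[[id]] <- zs
    }
  }
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  tops <- ids
  R <- if (length(filled)) sort(Reduce(intersect, sets[filled])) else character()
  n_inferred <- 0L

  # bottom-up agglomeration: repeatedly join the pair of subtree roots
  # sharing the largest common subset strictly beyond the global root set.
  # Ties break on mutation-set content alone (smallest intersection key,
  # then smallest member-set keys), so zone relabeling never reshapes the
  # topology.
  setkey <- function(s) paste(sort(s), collapse = ",")
  while (length(tops) > 1) {
    best <- NULL
    best_I <- NULL
    best_key <- NULL
    for (i in seq_along(tops)) {
      for (j in seq_along(tops)) {
        if (j <= i) next
        I <- intersect(node_sets[[tops[i]]], node_sets[[tops[j]]])
        if (length(I) <= length(R)) next  # R is a subset of every set, so this tests I != R
        members <- sort(c(setkey(node_sets[[tops[i]]]), setkey(node_sets[[tops[j]]])))
        key <- paste(setkey(I), members[1], members[2], sep = "|")
        if (is.null(best) || length(I) > length(best_I) ||
            (length(I) == length(best_I) && key < best_key)) {
          best <- c(i, j)
          best_I <- I
          best_key <- key
        }
      }
    }
    if (is.null(best)) break
    a <- tops[best[1]]
    b <- tops[best[2]]
    I <- sort(best_I)
    if (setequal(I, node_sets[[a]])) {
      parent[b] <- a
      tops <- setdiff(tops, b)
    } else if (setequal(I, node_sets[[b]])) {
      parent[a] <- b
      tops <- setdiff(tops, a)
    } else {
      anc <- NULL
      for (t in setdiff(tops, c(a, b))) {
        if (setequal(node_sets[[t]], I)) { anc <- t; break }
      }
      if (is.null(anc)) {
        n_inferred <- n_inferred + 1L
        anc <- sprintf("A%d", n_inferred)
        ids <- c(ids, anc)
        node_sets[[anc]] <- I
        node_zones[[anc]] <- character()
        parent[anc] <- NA_character_
        tops <- c(tops, anc)
      }
      parent[a] <- anc
      parent[b] <- anc
      tops <- setdiff(tops, c(a, b))
    }
  }

  # root of the mutated subtree: the node carrying exactly the intersection
  # of all non-empty zone sets, inferred if no sequenced node carries it
  sub_root <- NULL
  if (length(tops)) {
    for (t in tops) if (setequal(node_sets[[t]], R)) { sub_root <- t; break }
    if (is.null(sub_root)) {
      n_inferred <- n_inferred + 1L
      sub_root <- sprintf("A%d", n_inferred)
      ids <- c(ids, sub_root)
      node_sets[[sub_root]] <- R
      node_zones[[sub_root]] <- character()
      parent[sub_root] <- NA_character_
    }
    for (t in setdiff(tops, sub_root)) parent[t] <- sub_root
  }

  if (length(empty_zones)) {
    eid <- paste(empty_zones, collapse = "+")
    ids <- c(ids, eid)
    node_sets[[eid]] <- character()
    node_zones[[eid]] <- empty_zones
    parent[eid] <- NA_character_
    if (empty_as_ancestor) {
      root <- eid
      if (!is.null(sub_root)) parent[sub_root] <- eid
    } else if (is.null(sub_root)) {
      root <- eid
    } else {
      root <- "Root"
      ids <- c(ids, root)
      node_sets[[root]] <- character()
      node_zones[[root]] <- character()
      parent[root] <- NA_character_
      parent[eid] <- root
      parent[sub_root] <- root
    }
  } else {
    root <- sub_root
  }

  gains <- stats::setNames(lapply(ids, function(id) {
    p <- parent[[id]]
    if (is.na(p)) character() else sort(setdiff(node_sets[[id]], node_sets[[p]]))
  }), ids)
  structure(list(nodes = ids, zones = node_zones, sets = node_sets,
                 parent = parent, gains = gains, root = root,
                 lesion = matrix$lesion),
            class = "clone_dendrogram")
}

#' @export
print.clone_dendrogram <- function(x, ...) {
  cat(sprintf("clone_dendrogram '%s': %d node(s)\n", x$lesion, length(x$nodes)))
  cat(to_newick(x), "\n")
  invisible(x)
}

dendrogram_children <- function(dendro, id) {
  dendro$nodes[!is.na(dendro$parent[dendro$nodes]) &
                 dendro$parent[dendro$nodes] == id]
}

#' Serialize a dendrogram to Newick text
#'
#' Zone (and clade) labels become tips or labelled internal nodes, inferred
#' ancestors internal node labels, and edge lengths the number of mutations
#' gained along each edge (0 for the root). The output parses with standard
#' Newick readers such as `ape::read.tree()`.
#'
#' @param dendro a `clone_dendrogram` from [infer_ancestry()].
#' @return a single Newick string, e.g. `"((Z2:1)Z1:0);"`.
#' @export
to_newick <- function(dendro) {
  stopifnot(inherits(dendro, "clone_dendrogram"))
  seen <- character()
  render <- function(id) {
    if (id %in% seen) stop("cycle detected in dendrogram", call. = FALSE)
    seen <<- c(seen, id)
    kids <- dendrogram_children(dendro, id)
    len <- if (id == dendro$root) 0L else length(dendro$gains[[id]])
    lbl <- gsub("[,;:() ]", "_", id)
    if (length(kids)) {
      sprintf("(%s)%s:%d", paste(vapply(kids, render, character(1)), collapse = ","),
              lbl, len)
    } else {
      sprintf("%s:%d", lbl, len)
    }
  }
  out <- paste0("(", render(dendro$root), ");")
  if (length(seen) != length(dendro$nodes)) {
    stop("dendrogram is not connected", call. = FALSE)
  }
  out
}

#' Intratumour heterogeneity fraction
#'
#' Percentage of somatic mutations not detectable across every zone of
#' their lesion: `100 x (# mutations absent from >= 1 zone) / (# mutations)`,
#' rounded to the nearest integer for reporting. A list of matrices is
#' pooled (cohort-level numerator and denominator).
#'
#' @param x a [mutation_zone_matrix()] or a list of them.
#' @return integer percent.
#' @export
heterogeneity_fraction <- function(x) {
  if (inherits(x, "mutation_zone_matrix")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, logical(1), "mutation_zone_matrix"))) {
    fail_field("x", "must be a mutation_zone_matrix or a list of them")
  }
  num <- 0L
  den <- 0L
  for (m in x) {
    den <- den + ncol(m$mat)
    num <- num + sum(colSums(!m$mat) > 0)
  }
  if (den == 0) stop("heterogeneity undefined with zero mutations", call. = FALSE)
  as.integer(round_half_up(100 * num / den))
}
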