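# Independent plain-loop re-evaluation of caller rules for one candidate;
# mirrors the published rule set directly, shares no code with the caller.
oracle_rules <- function(t_alt, t_total, n_alt, n_total, in_germline = FALSE,
                         min_alt = 2, t_min = 0.02, n_max = 0.01) {
  t_frac <- if (t_total > 0) t_alt / t_total else 0
  n_frac <- if (n_total > 0) n_alt / n_total else 0
  if (t_frac < t_min) return("ii")
  if (t_alt < min_alt) return("i")
  if (n_frac > n_max) return("iii")
  if (t_total == 0 || n_total == 0) return("iv")
  if (in_germline) return("germline")
  "accepted"
}

# Independent re-coding of the containment/ancestry rule on plain string
# sets, used to cross-check infer_ancestry. Returns a canonical description:
# sorted "parent -> child" edges plus the root, each node identified by its
# content (mutation set | member zones).
oracle_ancestry_edges <- function(sets) {
  keyof <- function(set, zones) {
    paste(paste(sort(set), collapse = ","), paste(sort(zones), collapse = ","),
          sep = "|")
  }
  zs <- names(sets)
  filled <- zs[vapply(sets, length, integer(1)) > 0]
  empties <- setdiff(zs, filled)
  node_set <- list()
  node_zone <- list()
  order_ids <- character()
  for (z in filled) {
    sig <- paste(sort(sets[[z]]), collapse = ",")
    if (is.null(node_set[[sig]])) {
      node_set[[sig]] <- sort(sets[[z]])
      node_zone[[sig]] <- z
      order_ids <- c(order_ids, sig)
    } else {
      node_zone[[sig]] <- c(node_zone[[sig]], z)
    }
  }
  R <- character()
  if (length(filled)) {
    R <- sets[[filled[1]]]
    for (z in filled[-1]) R <- R[R %in% sets[[z]]]
    R <- sort(R)
  }
  parent <- list()
  tops <- order_ids
  n_inf <- 0
  while (length(tops) > 1) {
    bi <- 0; bj <- 0; bI <- NULL; bkey <- NULL
    for (i in seq_along(tops)) for (j in seq_along(tops)) {
      if (j <= i) next
      I <- node_set[[tops[i]]][node_set[[tops[i]]] %in% node_set[[tops[j]]]]
      if (length(I) <= length(R)) next
      mk <- sort(c(paste(sort(node_set[[tops[i]]]), collapse = ","),
                   paste(sort(node_set[[tops[j]]]), collapse = ",")))
      key <- paste(paste(sort(I), collapse = ","), mk[1], mk[2], sep = "|")
      if (is.null(bI) || length(I) > length(bI) ||
          (length(I) == length(bI) && key < bkey)) {
        bi <- i; bj <- j; bI <- I; bkey <- key
      }
    }
    if (is.null(bI)) break
    a <- tops[bi]; b <- tops[bj]; I <- sort(bI)
    if (identical(I, node_set[[a]])) {
      parent[[b]] <- a; tops <- tops[tops != b]
    } else if (identical(I, node_set[[b]])) {
      parent[[a]] <- b; tops <- tops[tops != a]
    } else {
      anc <- NULL
      for (t in tops) {
        if (t != a && t != b && identical(node_set[[t]], I)) { anc <- t; break }
      }
      if (is.null(anc)) {
        n_inf <- n_inf + 1
        anc <- sprintf("inf%d", n_inf)
        node_set[[anc]] <- I
        node_zone[[anc]] <- character()
        tops <- c(tops, anc)
      }
      parent[[a]] <- anc; parent[[b]] <- anc
      tops <- tops[!tops %in% c(a, b)]
    }
  }
  sub_root <- NULL
  if (length(tops)) {
    for (t in tops) if (identical(node_set[[t]], R)) { sub_root <- t; break }
    if (is.null(sub_root)) {
      sub_root <- "infroot"
      node_set[[sub_root]] <- R
      node_zone[[sub_root]] <- character()
    }
    for (t in tops) if (t != sub_root) parent[[t]] <- sub_root
  }
  root <- sub_root
  if (length(empties)) {
    eid <- "emptyclade"
    node_set[[eid]] <- character()
    node_zone[[eid]] <- empties
    if (is.null(sub_root)) {
      root <- eid
    } else {
      root <- "syntheticroot"
      node_set[[root]] <- character()
      node_zone[[root]] <- character()
      parent[[eid]] <- root
      parent[[sub_root]] <- root
    }
  }
  edges <- vapply(names(parent), function(ch) {
    paste(keyof(node_set[[parent[[ch]]]], node_zone[[parent[[ch]]]]),
          keyof(node_set[[ch]], node_zone[[ch]]), sep = " -> ")
  }, character(1))
  list(edges = sort(unname(edges)),
       root = keyof(node_set[[root]], node_zone[[root]]))
}

# Content-keyed edges of a clone_dendrogram, comparable to the oracle's.
dendro_edges <- function(d) {
  keyof <- function(id) {
    paste(paste(sort(d$sets[[id]]), collapse = ","),
          paste(sort(d$zones[[id]]), collapse = ","), sep = "|")
  }
  kids <- d$nodes[!is.na(d$parent[d$nodes])]
  edges <- vapply(kids, function(ch) {
    paste(keyof(d$parent[[ch]]), keyof(ch), sep = " -> ")
  }, character(1))
  list(edges = sort(unname(edges)), root = keyof(d$root))
}

# Ordered zone pairs (a, b) where a is a (transitive) ancestor of b in a
# dendrogram; clade co-members are not ancestors of each other.
dendro_ancestor_pairs <- function(d) {
  node_of <- list()
  for (id in d$nodes) for (z in d$zones[[id]]) node_of[[z]] <- id
  zs <- unlist(d$zones, use.names = FALSE)
  pairs <- character()
  for (a in zs) for (b in zs) {
    if (a == b) next
    anc <- node_of[[b]]
    repeat {
      anc <- d$parent[[anc]]
      if (is.na(anc)) break
      if (anc == node_of[[a]]) { pairs <- c(pairs, paste(a, b)); break }
    }
  }
  sort(pairs)
}
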