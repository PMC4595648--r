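test_that("presence matrices deduplicate by variant identity and drop silent calls", {
  call_row <- function(pos, alt = "G", status = "accepted", consequence = "missense") {
    data.frame(contig = "c1", pos = pos, ref = "A", alt = alt, gene = "G1",
               status = status, consequence = consequence, stringsAsFactors = FALSE)
  }
  m1 <- build_matrix(list(Z1 = rbind(call_row(1), call_row(2))))
  expect_equal(dim(m1$mat), c(1L, 2L))
  expect_true(all(m1$mat))

  m2 <- build_matrix(list(Z1 = call_row(1), Z2 = rbind(call_row(1), call_row(2))))
  expect_identical(unname(m2$mat), rbind(c(TRUE, FALSE), c(TRUE, TRUE)))

  # the same call observed in two zones yields a single column
  m3 <- build_matrix(list(Z1 = call_row(1), Z2 = call_row(1)))
  expect_equal(ncol(m3$mat), 1L)

  # silent / intronic / rejected calls never enter the matrix
  m4 <- build_matrix(list(Z1 = rbind(call_row(1),
                                     call_row(2, consequence = "silent"),
                                     call_row(3, status = "rejected"))))
  expect_equal(ncol(m4$mat), 1L)
})

test_that("containment chains, inferred precursors and empty zones order correctly", {
  chain <- infer_ancestry(matrix_from_sets(list(Z1 = "a", Z2 = c("a", "b"),
                                                Z3 = c("a", "b", "c"))))
  expect_equal(chain$root, "Z1")
  expect_equal(chain$parent[["Z2"]], "Z1")
  expect_equal(chain$parent[["Z3"]], "Z2")
  expect_equal(chain$gains[["Z2"]], "b")
  expect_equal(chain$gains[["Z3"]], "c")

  fork <- infer_ancestry(matrix_from_sets(list(Z1 = c("a", "b"), Z2 = c("a", "c"))))
  expect_equal(fork$root, "A1")
  expect_equal(fork$sets[["A1"]], "a")
  expect_equal(fork$parent[["Z1"]], "A1")
  expect_equal(fork$parent[["Z2"]], "A1")
  expect_equal(fork$gains[["Z1"]], "b")
  expect_equal(fork$gains[["Z2"]], "c")

  emp <- infer_ancestry(matrix_from_sets(list(Z1 = character(), Z2 = "a")))
  expect_equal(emp$root, "Root")
  expect_equal(emp$parent[["Z1"]], "Root")
  expect_equal(emp$parent[["Z2"]], "Root")
  expect_equal(emp$gains[["Z2"]], "a")
  expect_equal(emp$gains[["Z1"]], character())

  # alternative reading: mutation-free zones ancestral to mutated ones
  anc <- infer_ancestry(matrix_from_sets(list(Z1 = character(), Z2 = "a")),
                        empty_as_ancestor = TRUE)
  expect_equal(anc$root, "Z1")
  expect_equal(anc$parent[["Z2"]], "Z1")

  # zones with identical non-empty sets merge into one clade node
  clade <- infer_ancestry(matrix_from_sets(list(Z1 = "a", Z2 = "a", Z3 = c("a", "b"))))
  expect_true("Z1+Z2" %in% clade$nodes)
  expect_equal(clade$root, "Z1+Z2")
})

test_that("ancestry agrees with the rule oracle on every 4-zone, 3-mutation matrix", {
  muts <- c("a", "b", "c")
  zones <- c("Z1", "Z2", "Z3", "Z4")
  combos <- expand.grid(rep(list(0:7), 4))
  subset_of <- function(code) muts[bitwAnd(code, c(1L, 2L, 4L)) > 0]
  oracle_mismatch <- 0L
  invariant_broken <- 0L
  for (row in seq_len(nrow(combos))) {
    sets <- lapply(as.integer(combos[row, ]), subset_of)
    names(sets) <- zones
    mzm <- matrix_from_sets(sets)
    d <- infer_ancestry(mzm)
    got <- dendro_edges(d)
    want <- oracle_ancestry_edges(sets)
    if (!identical(got$edges, want$edges) || !identical(got$root, want$root)) {
      oracle_mismatch <- oracle_mismatch + 1L
    }
    # structural invariants on every output
    ok <- setequal(unlist(d$zones, use.names = FALSE), zones)
    for (id in d$nodes) {
      p <- d$parent[[id]]
      if (!is.na(p)) {
        ok <- ok && all(d$sets[[p]] %in% d$sets[[id]]) &&
          setequal(d$gains[[id]], setdiff(d$sets[[id]], d$sets[[p]]))
      }
    }
    filled <- names(sets)[lengths(sets) > 0]
    if (length(filled) && length(d$sets[[d$root]])) {
      ok <- ok && setequal(d$sets[[d$root]], Reduce(intersect, sets[filled]))
    }
    if (!ok) invariant_broken <- invariant_broken + 1L
  }
  expect_equal(oracle_mismatch, 0L)
  expect_equal(invariant_broken, 0L)
})

test_that("zone relabeling permutes but never reshapes the topology", {
  set.seed(55)
  for (rep in 1:20) {
    sets <- lapply(1:4, function(i) sample(letters[1:5], sample(0:4, 1)))
    names(sets) <- c("Z1", "Z2", "Z3", "Z4")
    d1 <- infer_ancestry(matrix_from_sets(sets))
    perm <- stats::setNames(sample(names(sets)), names(sets))
    relabeled <- stats::setNames(sets, unname(perm))
    relabeled <- relabeled[order(names(relabeled))]
    d2 <- infer_ancestry(matrix_from_sets(relabeled))
    # mutation-set-only edges pin the topology regardless of labels
    set_edges <- function(d) {
      kids <- d$nodes[!is.na(d$parent[d$nodes])]
      sort(unname(vapply(kids, function(ch) {
        paste(paste(sort(d$sets[[d$parent[[ch]]]]), collapse = ","),
              paste(sort(d$sets[[ch]]), collapse = ","), sep = " -> ")
      }, character(1))))
    }
    expect_identical(set_edges(d1), set_edges(d2))
    # clade membership maps through the permutation (multiset of
    # set-plus-member descriptions, d1's zones pushed through perm)
    describe <- function(d, zone_map) {
      sort(unname(vapply(d$nodes, function(id) {
        zs <- d$zones[[id]]
        if (!is.null(zone_map) && length(zs)) zs <- unname(zone_map[zs])
        paste(paste(sort(d$sets[[id]]), collapse = ","),
              paste(sort(zs), collapse = ","), sep = "||")
      }, character(1))))
    }
    expect_identical(describe(d1, perm), describe(d2, NULL))
  }
})

test_that("newick serialization round-trips through ape", {
  single <- infer_ancestry(matrix_from_sets(list(Z1 = "a")))
  expect_equal(to_newick(single), "(Z1:0);")

  chain <- infer_ancestry(matrix_from_sets(list(Z1 = "a", Z2 = c("a", "b"))))
  expect_equal(to_newick(chain), "((Z2:1)Z1:0);")

  four <- infer_ancestry(matrix_from_sets(list(
    Z1 = c("t1", "t2"), Z2 = c("t1", "t2", "b1"),
    Z3 = c("t1", "t2", "b1", "p1"), Z4 = c("t1", "t2", "p2"))))
  txt <- to_newick(four)
  tr <- ape::read.tree(text = txt)
  expect_s3_class(tr, "phylo")
  expect_setequal(intersect(c(tr$tip.label, tr$node.label),
                            c("Z1", "Z2", "Z3", "Z4")),
                  c("Z1", "Z2", "Z3", "Z4"))
  # serialize -> parse -> serialize is stable
  expect_equal(ape::write.tree(tr), ape::write.tree(ape::read.tree(text = txt)))
  # per-edge lengths are the gained-mutation counts
  expect_equal(sum(tr$edge.length), sum(lengths(four$gains)))
})

test_that("heterogeneity counts mutations missing from at least one zone", {
  all_true <- matrix_from_sets(list(Z1 = c("a", "b"), Z2 = c("a", "b")))
  expect_equal(heterogeneity_fraction(all_true), 0L)

  mixed <- matrix_from_sets(list(Z1 = c("t", "p1"), Z2 = c("t", "p2")))
  expect_equal(heterogeneity_fraction(mixed), 67L)  # 2 of 3 not ubiquitous

  # 21 mutations, 4 ubiquitous: 17/21 = 80.95 -> 81
  m <- matrix(FALSE, 3, 21)
  m[, 1:4] <- TRUE
  m[1, 5:21] <- TRUE
  big <- mutation_zone_matrix(c("Z1", "Z2", "Z3"), sprintf("m%d", 1:21), m)
  expect_equal(heterogeneity_fraction(big), 81L)

  empty <- mutation_zone_matrix("Z1", character(), matrix(FALSE, 1, 0))
  expect_error(heterogeneity_fraction(empty), "zero mutations")
})

test_that("calling plus ordering recovers simulated zone presence and ancestry", {
  cfg <- simulation_config(random_seed = 1234)
  cohort <- simulate_cohort(10, cfg)
  presence_hits <- 0L
  presence_total <- 0L
  relation_hits <- 0L
  relation_total <- 0L
  for (les in cohort) {
    calls <- lapply(les$tallies$tumor, function(tt) {
      annotate_consequence(call_somatic(tt, les$tallies$normal), cfg$panel)
    })
    mzm <- build_matrix(calls)
    zones <- names(les$tree$zone_composition)
    loci <- les$tallies$loci
    key_of <- stats::setNames(
      paste(loci$gene, loci$contig, loci$pos, loci$ref, loci$alt, sep = ":"),
      loci$mutation)
    inferred_sets <- lapply(zones, function(z) mzm$mutations[mzm$mat[z, ]])
    names(inferred_sets) <- zones
    true_sets <- lapply(zones, function(z) {
      unname(key_of[les$truth$mutations[les$truth$cellular_fraction[, z] > 0]])
    })
    names(true_sets) <- zones
    for (z in zones) {
      for (k in key_of) {
        presence_total <- presence_total + 1L
        presence_hits <- presence_hits +
          ((k %in% inferred_sets[[z]]) == (k %in% true_sets[[z]]))
      }
    }
    for (a in zones) for (b in zones) {
      if (a == b) next
      relation_total <- relation_total + 1L
      true_rel <- all(true_sets[[a]] %in% true_sets[[b]]) &&
        !setequal(true_sets[[a]], true_sets[[b]])
      inf_rel <- all(inferred_sets[[a]] %in% inferred_sets[[b]]) &&
        !setequal(inferred_sets[[a]], inferred_sets[[b]])
      relation_hits <- relation_hits + (true_rel == inf_rel)
    }
    # the dendrogram realises exactly the containment relations of its matrix
    d <- infer_ancestry(mzm)
    for (p in dendro_ancestor_pairs(d)) {
      ab <- strsplit(p, " ")[[1]]
      if (!all(ab %in% zones)) next
      expect_true(all(inferred_sets[[ab[1]]] %in% inferred_sets[[ab[2]]]))
    }
  }
  expect_gte(presence_hits / presence_total, 0.95)
  expect_gte(relation_hits / relation_total, 0.95)
})
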