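test_that("tally counts each distinct fragment once and applies filters", {
  # two observations from the same fragment collapse to one alternate pair
  obs <- rbind(make_obs("G", "f1"), make_obs("G", "f1"))
  t1 <- tally_observations(obs, "tumor")
  expect_equal(t1$alt_distinct_pairs, 1L)
  expect_equal(t1$total_distinct_pairs, 1L)

  # 5 paired passing observations (3 alt, 2 ref) + 1 unpaired alt
  obs <- rbind(make_obs("G", "f1"), make_obs("G", "f2"), make_obs("G", "f3"),
               make_obs("A", "f4"), make_obs("A", "f5"),
               make_obs("G", "f6", is_paired = FALSE))
  t2 <- tally_observations(obs, "tumor")
  expect_equal(t2$alt_distinct_pairs, 3L)
  expect_equal(t2$total_distinct_pairs, 5L)

  # phred cutoffs are strict: exactly 30 fails in tumour, passes in normal
  obs30 <- make_obs("G", "f1", min_phred = 30)
  expect_equal(nrow(tally_observations(obs30, "tumor")), 0L)
  expect_equal(tally_observations(obs30, "normal")$alt_distinct_pairs, 1L)
  expect_equal(nrow(tally_observations(make_obs("G", "f1", min_phred = 20), "normal")), 0L)

  # quality-failed and poorly mapped observations are excluded
  expect_equal(nrow(tally_observations(make_obs("G", "f1", is_quality_pass = FALSE), "tumor")), 0L)
  expect_equal(nrow(tally_observations(make_obs("G", "f1", mapq = 10), "tumor")), 0L)

  # reference-only loci keep their coverage with a "." alt
  t3 <- tally_observations(rbind(make_obs("A", "f1"), make_obs("A", "f2")), "normal")
  expect_equal(t3$alt, ".")
  expect_equal(t3$total_distinct_pairs, 2L)
})

test_that("caller applies rules i-iv, germline and coverage checks", {
  n0 <- make_tally(0, 80, "normal")

  ok <- call_somatic(make_tally(3, 100), n0)
  expect_equal(ok$status, "accepted")
  expect_equal(ok$fractional_abundance, 3.0)

  r2 <- call_somatic(make_tally(1, 100), n0)
  expect_equal(r2$rule, "ii")  # 1% < 2%

  r1 <- call_somatic(make_tally(1, 20), n0)
  expect_equal(r1$rule, "i")   # 5% passes the fraction rule, count fails

  r3 <- call_somatic(make_tally(10, 100), make_tally(2, 100, "normal"))
  expect_equal(r3$rule, "iii") # 2% > 1% in normal

  r4 <- call_somatic(make_tally(10, 100), make_tally(0, 0, "normal"))
  expect_equal(r4$rule, "iv")  # position not covered in the normal

  db <- germline_db(data.frame(contig = "c1", pos = 100, ref = "A", alt = "G"))
  rg <- call_somatic(make_tally(10, 100), n0, germline = db)
  expect_equal(rg$rule, "germline")

  # boundary semantics: exactly 2% tumour passes, exactly 1% normal passes
  expect_equal(call_somatic(make_tally(2, 100), n0)$status, "accepted")
  expect_equal(call_somatic(make_tally(10, 100), make_tally(1, 100, "normal"))$status,
               "accepted")

  expect_error(call_somatic(make_tally(3, 100), make_tally(0, 80, "normal", pos = 101)),
               "different loci")
})

test_that("caller matches brute-force rule evaluation on small tables", {
  set.seed(401)
  db <- germline_db(data.frame(contig = "c1", pos = 7, ref = "A", alt = "G"))
  for (rep in 1:25) {
    n_loci <- sample(1:20, 1)
    t_tot <- sample(0:120, n_loci, replace = TRUE)
    t_alt <- vapply(t_tot, function(n) sample(0:n, 1), integer(1))
    n_tot <- sample(0:120, n_loci, replace = TRUE)
    n_alt <- vapply(n_tot, function(n) sample(0:n, 1), integer(1))
    tum <- make_tally(t_alt, t_tot, pos = seq_len(n_loci))
    nor <- make_tally(n_alt, n_tot, "normal", pos = seq_len(n_loci))
    calls <- call_somatic(tum, nor, germline = db)
    for (i in seq_len(n_loci)) {
      want <- oracle_rules(t_alt[i], t_tot[i], n_alt[i], n_tot[i],
                           in_germline = (i == 7))
      got <- if (calls$status[i] == "accepted") "accepted" else calls$rule[i]
      expect_identical(got, want)
    }
  }
})

test_that("raising any threshold never enlarges the accepted set", {
  set.seed(402)
  t_tot <- sample(10:200, 60, replace = TRUE)
  t_alt <- rbinom(60, t_tot, runif(60, 0, 0.2))
  n_tot <- sample(10:200, 60, replace = TRUE)
  n_alt <- rbinom(60, n_tot, 0.01)
  tum <- make_tally(t_alt, t_tot, pos = 1:60)
  nor <- make_tally(n_alt, n_tot, "normal", pos = 1:60)
  accepted <- function(th) {
    calls <- call_somatic(tum, nor, thresholds = th)
    calls$pos[calls$status == "accepted"]
  }
  base <- accepted(caller_thresholds())
  stricter <- list(caller_thresholds(min_alt_pairs = 4),
                   caller_thresholds(tumor_fraction_min = 0.05),
                   caller_thresholds(normal_fraction_max = 0.005))
  for (th in stricter) expect_true(all(accepted(th) %in% base))
})

test_that("no accepted call survives at a germline-database locus", {
  set.seed(403)
  tum <- make_tally(rbinom(30, 100, 0.2), rep(100L, 30), pos = 1:30)
  nor <- make_tally(rep(0L, 30), rep(100L, 30), "normal", pos = 1:30)
  db <- germline_db(data.frame(contig = "c1", pos = c(3, 11, 25),
                               ref = "A", alt = "G"))
  calls <- call_somatic(tum, nor, germline = db)
  expect_false(any(calls$pos[calls$status == "accepted"] %in% c(3, 11, 25)))
})

test_that("fractional abundance reports one rounded decimal", {
  expect_equal(fractional_abundance(0, 50), 0.0)
  expect_equal(fractional_abundance(13, 100), 13.0)
  expect_equal(fractional_abundance(7, 33), 21.2)
  expect_equal(fractional_abundance(make_tally(13, 100)), 13.0)
  expect_error(fractional_abundance(0, 0), "undefined")
})

test_that("consequence classification follows the reading frame", {
  m <- tiny_model()
  call_at <- function(pos, ref, alt) {
    cand <- make_tally(10, 100, contig = "ctg1", pos = pos, ref = ref, alt = alt)
    nor <- make_tally(0, 100, "normal", contig = "ctg1", pos = pos, ref = ref, alt = alt)
    annotate_consequence(call_somatic(cand, nor), m)
  }
  mis <- call_at(15, "G", "A")    # GGT -> GAT
  expect_equal(mis$consequence, "missense")
  expect_equal(mis$status, "accepted")
  expect_equal(mis$gene, "GA")

  sil <- call_at(16, "T", "C")    # GGT -> GGC, third position
  expect_equal(sil$consequence, "silent")
  expect_equal(sil$status, "rejected")
  expect_equal(sil$rule, "consequence")

  non <- call_at(17, "A", "T")    # AAA -> TAA
  expect_equal(non$consequence, "nonsense")

  # minus-strand gene: genomic G>T at 45 is coding CCC -> CCA
  expect_equal(call_at(45, "G", "T")$consequence, "silent")

  expect_equal(call_at(14, "GG", "-")$consequence, "frameshift")
  expect_equal(call_at(14, "GGT", "-")$consequence, "inframe-indel")

  expect_equal(call_at(37, "C", "A")$consequence, "splice")
  expect_equal(call_at(44, "C", "A")$consequence, "splice")
  intr <- call_at(40, "C", "A")
  expect_equal(intr$consequence, "intronic")
  expect_equal(intr$status, "rejected")

  off <- call_at(5, "C", "A")
  expect_equal(off$rule, "off-target")
  expect_equal(off$status, "rejected")
})
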