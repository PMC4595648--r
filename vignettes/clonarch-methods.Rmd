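---
title: "Methods: clonal ordering and liquid-biopsy quantification in early lung neoplasia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal ordering and liquid-biopsy quantification in early lung neoplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

clonarch implements the computational chain used in multi-region targeted
sequencing studies of early lung glandular neoplasia — atypical adenomatous
hyperplasia (AAH), adenocarcinoma in situ (AIS) and minimally invasive
adenocarcinoma (MIA) — together with droplet digital PCR (ddPCR)
quantification of the same mutations in circulating DNA. This vignette is
the package's account of the underlying models, the tunable parameters, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not establish about real data.

## Somatic calling from distinct read-pair tallies

The counting unit throughout is the *distinct read pair*: deduplicated
paired-read fragments, identified by a fragment signature, each counted
once per locus. `tally_observations()` applies the alignment filter
(unpaired, quality-failed and poorly mapped observations are excluded) and
a strict base-quality filter — phred > 30 in the tumour, > 20 in the
matched normal — before collapsing by fragment signature. "Poorly mapped"
is not standardised anywhere; the package uses mapping quality < 20, the
usual short-read convention, exposed as `min_mapq`.

`call_somatic()` then accepts a candidate only when all of the following
hold, with defaults in `caller_thresholds()`:

* at least 2 distinct alternate pairs (rule i; the threshold is exposed
  because "a few supporting fragments" is assay-dependent);
* an alternate fraction of at least 2% of total distinct pairs (rule ii,
  inclusive: exactly 2% passes);
* a matched-normal alternate fraction of at most 1% (rule iii, inclusive:
  exactly 1% passes) and no hit in the germline exclusion database;
* coverage in both tumour and normal (rule iv).

Rejections carry the first failing rule code, with one deliberate wrinkle:
when both the count rule and the fraction rule fail (say 1 alternate pair
in 100), the rejection is coded `ii`, because at ordinary panel depths the
2% rule is the binding constraint and the count rule exists only to guard
very low-depth loci. The 2% rule is applied per locus; region-level
aggregation would need assay information the tally dialect does not carry.

Consequence annotation (`annotate_consequence()`) is a deliberately small
classifier, not a full effect predictor: SNVs are translated through the
panel's reading frame (missense / nonsense / silent), indels classified by
length modulo 3, positions within 2 nt of an interior CDS edge are splice,
and positions inside the gene footprint but outside the CDS are intronic.
Silent and intronic calls are demoted to rejections, mirroring the
filtering convention of panel pipelines. Fractional abundance is
`100 x alt / total`, carried at full precision and rounded half-up to one
decimal only for reporting.

## Copy number from coverage ratios

`call_cna()` compares normalized average per-base coverage per gene between
tumour and matched normal. Normalization divides by the sample-wide mean
gene coverage (the plainest reading of "normalized average"; a median
option exists for robustness). No fold-change cutoffs are standard for
this design, so the defaults are the conventional log2 ±1: ratio ≥ 2
amplification, ≤ 0.5 deletion. For a gene at `n` copies in a tumour of
purity `p` the expected ratio is `1 + p(n − 2)/2`, so these defaults
demand high-level events — a 4-copy gain at purity 0.6 (expected ratio
1.6) is deliberately left neutral.

## Clonal ordering across lesion zones

Zones are spatially and histologically defined regions of one lesion (3
for AIS, 4 for MIA, the fourth being the invasive core). The ordering rule
is containment: a zone containing all mutations observed in another zone
is its ancestor; where no such zone exists, putative precursors are
inferred from the alterations common to multiple zones. `infer_ancestry()`
realises this as a bottom-up agglomeration: repeatedly join the two
subtree roots sharing the largest common mutation subset strictly beyond
the global root set (the intersection of all non-empty zone sets), making
the smaller set the parent when the pair is nested and otherwise creating
an inferred-ancestor node holding the intersection.

Three situations the containment rule leaves open are resolved as follows:

* **Several candidate ancestors.** The candidate with the largest mutation
  set wins — the closest ancestor. This falls out of the
  largest-subset-first join order rather than being a special case.
* **Zones with identical non-empty sets.** Merged into a single clade
  node rather than chained in arbitrary order; an arbitrary chain would
  assert an ordering the data cannot support.
* **Ties between joins.** Broken on mutation-set content alone
  (lexicographically smallest intersection, then member sets), never on
  zone labels, so relabeling zones can permute but never reshape a
  dendrogram. This is asserted property-style in the test suite.

Zones with no alterations attach as parallel branches at the root by
default; `empty_as_ancestor = TRUE` implements the alternative reading in
which a mutation-free zone is ancestral to the mutated ones. The
heterogeneity statistic is the percentage of mutations absent from at
least one zone of their lesion, reported as a nearest integer; a list of
matrices pools numerators and denominators cohort-wide.

`to_newick()` serializes dendrograms with edge lengths equal to gained
mutation counts; the root edge is written as length 0. Output parses with
`ape::read.tree()`, which the tests use as the independent round-trip
reference.

## ddPCR Poisson quantification

Templates partitioned into `n` droplets follow Poisson occupancy: with
`k` positive droplets, the mean occupancy is `λ = −ln(1 − k/n)` and the
concentration `λ/v` scaled to copies per µl (`v` in nl, default 1 nl for
the ~1 nl emulsion droplets; instrument calibrations such as 0.85 nl can
be supplied). The 95% CI is a delta-method interval,
`SE(λ) = sqrt(k / (n(n − k)))`, floored at zero — an explicit
approximation, since instrument software does not publish its interval
method. Mutant fractional abundance `100·c_m/(c_m + c_w)` propagates both
channel SEs by the delta method and is exactly invariant to a common
volume rescaling.

Detection is `mutant_positive ≥ 3` droplets by default; published fluid
studies do not state their gate, so the threshold is a parameter.
`lod_series()` simulates a serial dilution (fractions sorted descending)
and reports the smallest fraction detected in at least 95% of replicates;
under the study conditions (20,000 droplets, 10,000 template copies —
roughly the haploid genome equivalents of a 35 ng background at 3.3 pg
per genome — and 200 replicates) 0.1% mutant DNA is reliably detected:
10 mutant copies land in ~10 distinct droplets, far above the 3-droplet
gate, so the detection rate at 0.1% is essentially 1.

## The synthetic cohort generator

The generator exists so that every downstream stage can be tested against
known truth without external data. Its defaults *are* the study
conditions: 4 zones, tumour purity 0.6 (microdissection to > 60%
neoplastic cells; per-lesion truth beyond that bound is unknown, so the
bound is taken as the default), mean distinct-pair depth 400× (panel
depths of roughly 400–485×), per-base error 0.1%, 3 truncal / 4 branch /
5 private mutations per lesion, and the ddPCR geometry above.

A clone tree is one truncal clone plus one leaf clone per zone, with
internal clones generated by a seeded recursive bipartition of the zone
set; truncal mutations sit on the root branch, branch mutations on
internal branches, private mutations round-robin across leaf branches.
Each zone's tumour cells are 100% its leaf clone, so true cellular
fractions are 0/1 — the simplest structure consistent with the
heterozygous single-copy model below. With two zones no internal branch
exists and branch mutations fall through to leaf branches.

Expected tumour alternate fraction at a mutated locus is
`purity × cellular_fraction × 0.5 + error`: a heterozygous single-copy
model. Ploidy is not observable from tally tables, and the factor 0.5 is
the simplest model consistent with observed fractional abundances of
≤ 35% at purities above 0.6. Distinct pairs are simulated directly —
deduplication is modelled as already done, since tally tables count
fragments, not raw reads. Total depth is Poisson around the mean,
alternate counts binomial. Germline heterozygous sites are not simulated
by default; rule iii is exercised by targeted tests instead. True fluid
fractions are drawn log-uniformly in [0.03%, 1%], bracketing reported
plasma and sputum mutant fractions.

All randomness flows from one mandatory master seed, with sub-streams
derived by stable hashing of (purpose, zone, locus, replicate) keys —
adding zones or lesions never perturbs existing draws, and identical
configurations are byte-identical.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: mapping and alignment artefacts
(paralogy, indel realignment), FFPE deamination damage, copy-number
distortion of allele fractions, germline contamination of the normal,
droplet "rain" and fluorescence-threshold ambiguity, and between-patient
variation in mutation burden. Recovery rates on synthetic cohorts are
upper bounds under the stated error model, not claims about archival
tissue.

## Numerical conventions and problem sizes

Coordinates are 1-based closed intervals; deletions use a `-` alternate
allele internally and are re-anchored VCF-style on output when reference
sequence is available. Percentages round half-up (80.95 → 81; the
heterogeneity statistics 81% and 83% are nearest-integer reports of 17/21
and 25/30). Zone-composition fractions must sum to 1 within 1e-9.

The test suite runs entirely on generated data: the ancestry rule is
checked exhaustively against an independently coded oracle on all 4096
4-zone × 3-mutation matrices; caller rules are cross-checked by
brute-force re-evaluation on random ≤ 20-locus tables; recovery
properties use cohorts of 6–10 lesions, 100-replicate droplet
simulations, and 1,000-locus sensitivity sweeps — sizes chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
standard errors far from the asserted bounds.

## Known limitations

* The consequence classifier handles SNVs and simple indels against a
  CDS-interval model; it does not model UTRs, alternative transcripts or
  compound substitutions, and classifies stop-loss as missense.
* The containment rule is combinatorial, not likelihood-based: it cannot
  express uncertainty, and with conflicting partial overlaps the greedy
  largest-subset-first order is one defensible resolution among several.
* Translocation calling is out of scope (panel designs mention them, but
  no tally-level method exists for them).
* The ddPCR CI is a large-sample approximation that undercovers slightly
  at very small `k`; the simulation-consistency test bounds this in
  practice.
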