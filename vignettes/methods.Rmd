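---
title: "Models and methods behind epireprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epireprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epireprog)
```

# The scientific setting

epireprog analyses longitudinal multi-omic designs built around an
early-life chemical exposure: animals are dosed as neonates with an
endocrine-disrupting chemical (EDC) or vehicle, and livers are profiled by
histone-mark ChIP-seq at the neonatal and adult timepoints, by RNA-seq, and
by targeted metabolomics/lipidomics after a later-life dietary challenge.
The central question is whether the exposure *accelerates* the normal
age-related remodelling of the epigenome rather than simply perturbing it.
The package starts from the processed outputs of standard upstream tools —
differential-region tables, a chromatin-state segmentation, a
differential-expression table, abundance matrices — and owns everything
downstream: annotation, classification, enrichment, recurrence selection and
reporting.

# Reprogramming classification

## Contrasts and strata

Three contrasts are compared per histone mark and per direction of change:
**A** (age: vehicle neonate vs vehicle adult — "normal" maturation is
defined on unexposed animals), **N** (neonatal: exposed vs vehicle neonates)
and **D** (adult: exposed vs vehicle adults). Classification operates
strictly within a (mark, direction) stratum; a gene gaining H3K4me1 in one
contrast and losing it in another contributes to two different strata and is
never merged, mirroring per-direction Venn analysis. Whether direction
concordance beyond set membership should be required is an open question in
this kind of design; the package deliberately uses membership only, which is
the weaker and more reproducible criterion.

## The truth table

The membership triple (A, N, D) has seven non-empty values, each mapped to
exactly one class (`PRECOCIOUS`, `EDC_SPECIFIC`, `CUMULATIVE`,
`LATER_ONSET`, `AGE_ONLY`, `NEONATAL_TRANSIENT`, `AGE_AND_ADULT`). The two
less-interpretable Venn regions receive explicit labels (`AGE_ONLY`,
`NEONATAL_TRANSIENT`, `AGE_AND_ADULT`) so that the classification is a
*total* function and the partition property — classes pairwise disjoint,
union equal to A ∪ N ∪ D — can be asserted on every run, which
`classify_reprogramming()` does.

## Annotation geometry

A differential region is assigned to a gene when it intersects the closed
window `[tss − w, tss + w]` with `w = 3000` bp by default; the window is
inclusive at both ends, matching the semantics of common interval-overlap
tools. Enhancer assignment requires a ≥ 1 bp overlap in half-open
coordinates, so adjacency is not overlap. All coordinates are normalized
once at load time to 0-based half-open form (diffReps-style tables are
1-based inclusive; BED already half-open); a single internal convention
prevents off-by-one drift, and a round-trip through BED is tested to leave
annotation invariant. Chromosome-name mismatches between inputs ("chr1" vs
"1") are an error rather than being silently harmonized; a rename map can be
supplied at load time.

## Significance filters

The differential-region loader filters at q < 0.01 and fold change
strictly exceeding 2× by default. A 1.5× variant is a legitimate alternative
definition of the differential peaks, so the threshold is a parameter rather
than a constant; the pipeline report always records the active values.

## Report arithmetic

Summary percentages (e.g. the share of age-associated features that were
precociously reprogrammed, `100·|PRECOCIOUS|/|A|`) are rounded half away
from zero to integers, the convention of `round_half_up()`. An empty
denominator yields an *undefined* percentage (`NA`), never 0. The
adult-signature count is `|PRECOCIOUS| + |CUMULATIVE|`: features whose adult
state was reached early plus those whose maturation change was exaggerated.

# Chromatin-state odds ratios

For a state occupying `s` bp of a `G`-bp genome and `k` of `n` distinct
regions overlapping it, the enrichment is

$$\mathrm{OR} = \frac{k/(n-k)}{s/(G-s)}.$$

Design choices, all recorded in the output: a region counts as "in" a state
if it overlaps any segment of it by ≥ 1 bp (it may count toward several
states; regions are not fractionally apportioned), duplicate regions are
collapsed by coordinates first, and when `k = 0` or `k = n` the
Haldane–Anscombe correction adds 0.5 to the two count cells. The size cells
cannot be zero by construction; a state covering nothing or the whole
genome has no defined enrichment and is reported as `NA` rather than a
number. A bp-weighted variant (overlap basepairs instead of region counts)
sits behind `unit = "bp"` because the count/bp choice is genuinely
underdetermined in this kind of analysis; counts are the default as the
closer match to overlap-tool semantics. The OR ≥ 100 flag marks states to
be read as primary reprogramming targets. `G` defaults to the sum of the
supplied chromosome sizes.

# Metabolite statistics

## Processing chain

1. **KNN imputation** (`knn_impute`, k = 5): neighbours are *features*;
   distances are root-mean-square differences over co-observed samples
   (scaling by the number of co-observed samples keeps sparse features
   comparable); only candidates observed in the target sample are eligible,
   and fewer than k available neighbours means all of them are used, with a
   message. Observed cells are never altered. k = 5 is a conventional
   choice for matrices of O(100) features; the imputation is deliberately
   simple and deterministic.
2. **log2 + day-median normalization**: abundances must be strictly
   positive (violations are an error, not a silent drop); after log2, the
   median of each acquisition day's entries is subtracted from that day's
   samples, centring every day at zero. With one day (or no day labels)
   this is global median centring.
3. **Per-feature t-test**: Welch by default — a robust default when group
   variances are not known to be equal — with the pooled-variance test
   behind a flag; two-sided; BH q-values over all tested features;
   significance at q < 0.25. Features with zero variance in both groups
   and equal means get t = 0, p = 1 by convention.
4. **z-scores**: each exposed sample's distance from the vehicle centre in
   vehicle standard deviations (sample SD, n − 1). The centre is the
   vehicle *mean* by default with the median behind a flag, since both
   centres are defensible for n = 5 reference animals; zero reference SD
   makes z undefined (`NA` plus a warning), never infinite.

## The recurrence rule

A metabolite is recurrently increased when z ≥ 1.5 in at least 3 exposed
animals *and* z ≤ −1.5 in none (mirror image for decreases); both
thresholds are inclusive. The rule is antisymmetric under z-negation — a
property the suite checks on random matrices — and is evaluated per feature
with no cross-feature pooling. With five exposed animals the rule tolerates
up to two non-responding animals but zero opposite responders, which is
what makes it a *recurrence* criterion rather than a mean-shift test.

# Hybrid set enrichment (MetSEA)

The differential-expression signature keeps genes with q < 0.1 and fold
change ≥ 1.25× or ≤ 0.8× (fold-change bounds inclusive, q strict). The
hybrid signature is its union with the recurrent metabolites; both are
restricted to the declared universe before testing. Enrichment per pathway
is the exact hypergeometric upper tail `P(X ≥ k)` — never a normal
approximation — with BH correction applied within the compendium being
tested, and results are sorted by (q, p, pathway id) so output is invariant
to input order. Feature kinds are encoded as `GENE:`/`MET:` namespaces in
pathway files and signatures, and gene/metabolite overlap counts are
reported separately per pathway. On gene-only input MetSEA reduces exactly
to plain over-representation analysis; the suite asserts this reduction.

The default significance threshold is q < 0.2, with the looser 0.25
variant configurable; both are echoed in the report, as is the universe
size `M` for every result, because the universe choice (all compendium
members vs measured features) dominates hypergeometric p-values and should
never be implicit. Identifier mapping between measured metabolite names and
pathway names is a user-supplied two-column map by design — automatic
chemical-name fuzzy matching is error-prone and out of scope.

# The synthetic-data generator

`simulate_study()` writes every pipeline input with a truth table beside
it. What it emulates: the three-contrast differential tables per mark with
classes planted per gene/enhancer; an abundance matrix with group and day
structure, missing values, and planted recurrent features in
vehicle-SD-calibrated effect units (default shift 3 SD in ≥ 3 exposed
samples, never opposite); a DE table whose planted rows pass the signature
thresholds and whose background rows fail both; and a hybrid compendium
with one planted pathway carrying planted DE genes and planted recurrent
metabolites.

The layout is slot-based: gene TSSs, enhancer midpoints and distractor
anchors sit on a common grid whose pitch exceeds twice the TSS window plus
the maximal region extent, so planted regions can only annotate to their
own feature and distractor regions annotate to nothing. State segments tile
each chromosome exactly (a partition, so per-state bp sums to the genome
size).

Two generator properties deserve emphasis:

* **Determinism.** Identical config + seed give byte-identical files; the
  suite compares emitted trees line by line.
* **Truth realization by constrained sampling.** With five vehicle
  animals, null z-scores are heavy-tailed (approximately scaled t with 4
  degrees of freedom), so an unconstrained generator would occasionally
  emit an unplanted feature that satisfies the recurrence rule by chance.
  The generator therefore verifies every feature against the package's own
  processing chain (impute → normalize → z → recurrence) and resamples the
  few violating features until the emitted matrix realizes the declared
  truth exactly — the same device as placing distractor regions two windows
  away from every TSS. The consequence to keep in mind: end-to-end recovery
  tests demonstrate the *plumbing* (loaders, normalization, thresholds,
  ranking) is faithful, not that the recurrence rule has perfect
  sensitivity/specificity on unconstrained data. The type-I behaviour of
  the t-test is checked separately on a genuinely unconstrained null
  simulation.

What the generator does not emulate: read-level data, realistic peak
shapes or widths, correlated features, heteroscedastic missingness
(missingness is uniform at the configured rate), multi-mark co-occurrence
at a locus, or inter-pathway overlap structure. Passing recovery tests
therefore say nothing about peak-calling quality or about recurrence-rule
operating characteristics on real cohorts.

Default scale — 2 chromosomes × 10 Mb, 500 genes, 200 enhancers, 8 states,
4 marks, 120 metabolite features, 5 + 5 samples over 2 acquisition days, 16
planted up / 10 planted down metabolites, 40 + 30 planted DE genes, 20
background pathways — generates in a few seconds and exercises every code
path; the test suite additionally uses a reduced configuration (60 genes,
50 features) for the many-seed property checks.

# Pipeline orchestration

`run_pipeline()` executes annotate → classify → state-enrich → omics-test →
recurrence → MetSEA from a single validated config (R list or YAML). Inputs
are validated before any stage runs; a stage failure writes a `FAILED`
marker and stops downstream stages while retaining partial outputs. Every
number in the consolidated `report.json`/`report.md` is recomputable from
the stage output files, and the report records all effective thresholds and
which of the documented alternatives (Welch vs pooled, mean vs median
centre, count vs bp odds ratios, fold-change cut) was active. Report
content is deterministic; wall-clock timings go only to `run.log`. The
package's function surface is the interface — the pipeline is driven from R
or from `Rscript -e` one-liners rather than a bespoke shell tool.

# Known limitations

* Classification is purely set-theoretic: no effect-size concordance
  across contrasts is required, and no uncertainty is propagated from the
  upstream differential calls.
* The odds-ratio construction treats regions as exchangeable counts;
  regions of very different widths contribute equally unless the bp unit
  is selected.
* KNN imputation assumes feature-neighbour similarity is informative; for
  matrices with very few features the neighbour pool is thin and imputed
  values are correspondingly coarse.
* The hypergeometric model assumes exchangeable draws from the universe;
  correlated gene sets or metabolite panels violate this, as they do for
  any over-representation analysis.
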