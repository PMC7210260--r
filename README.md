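# epireprog

Integrative multi-omic analysis of **accelerated epigenomic aging after an
early-life endocrine-disrupting chemical (EDC) exposure**. The package is
aimed at epigenomics groups running longitudinal designs in which animals are
exposed as neonates and profiled (ChIP-seq, RNA-seq, metabolomics/lipidomics)
both immediately after exposure and in adulthood, and who want to ask: *did
the exposure merely perturb the epigenome, or did it accelerate the normal
age-related remodelling of it?*

## What it computes

**1. Reprogramming classification.** For each histone mark (H3K4me1,
H3K4me3, H3K27ac, H3K27me3) and direction of change, differential regions
from three contrasts are mapped to genes (differential peak within ±3 kb of
the TSS, inclusive) and to enhancers (≥1 bp overlap):

- **A** — normal maturation (vehicle neonate vs vehicle adult),
- **N** — acute exposure effect (neonate EDC vs vehicle),
- **D** — persistent adult effect (adult EDC vs vehicle).

Each feature in A ∪ N ∪ D receives exactly one of seven disjoint classes
determined by its membership triple (A, N, D):

| (A, N, D) | class | meaning |
|---|---|---|
| 1 1 0 | `PRECOCIOUS` | exposure pre-installs the adult signature; adults indistinguishable from controls |
| 0 1 1 | `EDC_SPECIFIC` | acute change persisting to adulthood, absent from normal maturation |
| 1 1 1 | `CUMULATIVE` | maturation change further exaggerated by exposure |
| 0 0 1 | `LATER_ONSET` | adult-only difference |
| 1 0 0 | `AGE_ONLY` | maturation change untouched by exposure |
| 0 1 0 | `NEONATAL_TRANSIENT` | acute change that resolves |
| 1 0 1 | `AGE_AND_ADULT` | age-associated and adult-different without an acute effect |

**2. Chromatin-state enrichment.** For differential regions against a
ChromHMM-style segmentation, the odds ratio per state is

OR = [k / (n − k)] / [s / (G − s)]

with `k` regions overlapping the state, `n` regions total, `s` the state's
cumulative bp and `G` the genome size (Haldane–Anscombe 0.5 correction when
`k` ∈ {0, n}); states with OR ≥ 100 are flagged as primary reprogramming
targets.

**3. Metabolite statistics.** Feature-wise processing of abundance
matrices: KNN imputation (neighbours are features), log2 + acquisition-day
median normalization, Welch t-tests with Benjamini–Hochberg FDR (q < 0.25),
and z-scores of each exposed animal against the vehicle mean/SD. The
**recurrence rule** selects metabolites with z ≥ 1.5 in ≥ 3 exposed animals
and ≤ −1.5 in none (or the mirror image).

**4. Hybrid enrichment (MetSEA).** A differential-expression gene signature
(q < 0.1, fold change ≥ 1.25× or ≤ 0.8×) is pooled with the recurrent
metabolites and tested against hybrid gene+metabolite pathways
(`GENE:`/`MET:` namespaces) with the exact hypergeometric upper tail
P(X ≥ k), X ~ Hypergeom(M, K, n), and BH FDR (q < 0.2).

**5. Synthetic studies.** `simulate_study()` generates every pipeline input
with planted ground truth — reprogramming classes per gene/enhancer,
recurrent metabolites, an enriched hybrid pathway — deterministically from a
seed, so the whole chain is testable end to end.

## Worked example

Classifying the H3K4me1-gain gene sets from a maturation contrast of 3436
genes, 3003 of which also change acutely under exposure:

```r
library(epireprog)
sets <- build_contrast_sets(
  age      = c(sprintf("p%04d", 1:3003), sprintf("a%04d", 1:433)),
  neonatal = sprintf("p%04d", 1:3003), adult = NULL,
  mark = "H3K4me1", direction = "up")
summarize_classes(classify_reprogramming(sets), sets)
#> Reprogramming summary [H3K4me1 up, gene]
#>   |A|=3436 |N|=3003 |D|=0
#>   PRECOCIOUS         3003
#>   EDC_SPECIFIC       0
#>   CUMULATIVE         0
#>   LATER_ONSET        0
#>   AGE_ONLY           433
#>   NEONATAL_TRANSIENT 0
#>   AGE_AND_ADULT      0
#>   precocious % of age-associated set: 87%
#>   adult-signature features (precocious + cumulative): 3003
```

The full pipeline on a synthetic study:

```r
sim_dir <- file.path(tempdir(), "demo"); out <- file.path(tempdir(), "demo_out")
simulate_study(sim_config(seed = 1), sim_dir)
run_pipeline(pipeline_config_from_simulation(sim_dir, seed = 1), out)
cat(readLines(file.path(out, "report.md")), sep = "\n")
#> # Pipeline report
#>
#> - differential tables: 12 (kept regions: 31, 79, 65, 43, 74, 73, 52, 98, 86, 36, 82, 76)
#> - class strata summarized: 16
#> - omics features tested: 120, significant at q<0.25: 20
#> - recurrent metabolites: 16 up, 10 down
#> - hybrid signature: 40 genes up, 30 down, 26 metabolites
#> - top MetSEA pathway: PW_planted (q = 0.000184)
#>
#> Active alternatives: t-test = Welch; z centre = mean; odds-ratio unit = count;
#> region thresholds q<0.01 FC>2x; enrichment q<0.2.
```

The report shows the generator's 16 recurrently increased and 10 recurrently
decreased metabolites recovered exactly, and the planted hybrid pathway
ranked first far below the q < 0.2 threshold. Per-stage outputs (annotation
sets, class calls, state odds ratios, t-tests, Oncoprint-style z tables,
enrichment tables) are written under stage-named subdirectories of `out`.

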