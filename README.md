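# enhdyn

Transcribed-enhancer discovery and enhancer–promoter interaction dynamics
across a neuronal differentiation time course, as a tidyverse-native R
package.

`enhdyn` is for computational biologists analysing 5′-end tag data (CAGE on
total RNA for promoters, nascent-RNA CAGE for enhancer RNAs) together with
capture Hi-C across a small number of differentiation stages. It implements:

* **Bidirectional enhancer calling** from stranded CTSS tag tables:
  single-linkage tag clustering, divergent-pair detection with the
  directionality score *D* = (F − R)/(F + R) and |D| < 0.8, promoter
  masking, and novelty classification against known enhancer catalogs.
* **Expression analysis**: strand-specific counting, log2 CPM with a 0.25
  prior count, expression filters (promoters log2 CPM > −2, enhancers
  > −2.5), a native negative binomial ANOVA-like timepoint test with
  moderated dispersion and Benjamini–Hochberg FDR, and k-means temporal
  clustering with deterministic relabeling onto early/late × up/down
  archetypes.
* **Capture Hi-C interaction calling** against an *empirical* background
  built from negative-control probes: ≥ 5 supporting pairs and
  Bonferroni-adjusted p ≤ 0.1 in both replicates; per-timepoint interaction
  networks and per-node rewiring statistics
  JI = |A∩B|/|A∪B| and OCE = |A∩B|/min(|A|,|B|).
* **GWAS-variant enrichment** with LD expansion (r² ≥ 0.7, 1 Mb window),
  ≥ 500 matched controls per index SNP and a permutation test; and
  novel-enhancer characterization: conservation, SNP density, nucleotide
  diversity π = 2·AF·(1−AF), eQTL overlap, against length-matched random
  regions.
* A **synthetic-data generator** that plants all of the above with known
  ground truth, so every stage is testable offline, plus qPCR 2^−ΔΔCt
  utilities and a run report whose percentages are recomputable from the
  integer counts stored beside them.

All user-facing functions take data frames first and return tibbles; fitted
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
helpers.

## Worked example

```r
library(enhdyn)

run <- run_pipeline(sim_config(seed = 3), n_permutations = 300)
run
#> enhdyn synthetic pipeline run (seed 3)
#>   bidirectional loci: 299 (35.1% known)
#>   DE promoters/enhancers: 89 / 33
#>   significant interactions: 84 (mean distance 37.6 kb)
#>   GWAS enrichment fold 3.05 (p = 0.00332)
```

The run simulates a 3-timepoint study (Day 1/3/6, two replicates, total- and
nascent-RNA assays) with 400 promoters and 300 planted enhancers. Reading
the output: 299 of the 300 planted bidirectional enhancers are recovered
from the nascent CTSS signal (35.1% overlap the simulated "known" catalog,
the rest are novel); 89 promoters and 33 enhancers are temporally
differentially expressed at FDR < 0.05 — fewer enhancers because their
expression is much lower; 84 chromatin interactions pass the
empirical-background caller in both replicates, and the planted 3× GWAS
enrichment in enhancers is recovered as a fold of 3.05 with permutation
p ≈ 0.003.

Individual stages compose with the pipe, e.g. calling enhancers by hand:

```r
truth <- gen_landscape(sim_config(seed = 3))
ctss  <- gen_ctss(truth, sim_config(seed = 3))
loci  <- ctss |>
  dplyr::filter(grepl("nascent", sample_id)) |>
  cluster_ctss() |>
  call_bidirectional(promoter_mask = truth$promoters)
```

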