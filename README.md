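# commassembly

Tools for asking *how a microbial community is put together*. Given an
OTU count table, a rooted phylogeny and a per-sample environmental
table, `commassembly` runs the community-ecology inference chain used
in microbiome studies of habitat specialisation and assembly:

* **abundant/rare partition** at the 0.01 % mean relative-abundance
  threshold, with alpha diversity (richness, Shannon, Pielou, Chao1,
  ACE), ANOVA/Tukey group letters and Bray–Curtis PCoA;
* **Levins' niche breadth** `B_j = 1 / Σ_i q_ij²` (with `q` the OTU's
  normalised distribution over the *N* communities, so `B ∈ [1, N]`),
  community means with bootstrap spread, and generalist / specialist /
  neutral classification against a count-preserving (quasiswap)
  permutation null;
* **assembly-process attribution** per sample pair: abundance-weighted
  βMNTD and its tip-shuffle standardised effect size βNTI, Raup–Crick
  on Bray–Curtis (RC_Bray), and the five-way scheme — βNTI ≥ 2
  heterogeneous selection, βNTI ≤ −2 homogeneous selection, else
  RC_Bray > 0.95 dispersal limitation, RC_Bray < −0.95 homogenising
  dispersal, |RC_Bray| ≤ 0.95 undominated;
* **co-occurrence networks** from all-pairs Spearman correlations
  (|r| > 0.8, p < 0.01, after a 2/3 prevalence filter) with the usual
  topology summary (average degree, clustering coefficient, path
  distance, density, modularity mean ± sd over restarts);
* **Mantel tests** (Spearman, permutation) relating βNTI to Euclidean
  distances of individual environmental variables.

A synthetic-community generator with selectable assembly regime
(neutral, two-environment selection, split-pool dispersal limitation),
log-normal core–satellite abundance structure and phylogenetically
conserved niche traits provides ground truth for validating every
stage, so the whole chain is testable without any sequencing download.

## Worked example

Simulate a 12-sample community assembled by two-environment selection,
attribute processes, and test the environmental association:

```r
library(commassembly)

cfg <- sim_config(regime = "selection", seed = 42)
ds  <- simulate_community(cfg)

asm <- assembly_processes(ds$table, ds$tree, n_null = 999, seed = 42)
round(asm$fractions, 2)
#> heterogeneous_selection   homogeneous_selection    dispersal_limitation
#>                    0.55                    0.00                    0.00
#>  homogenizing_dispersal             undominated
#>                    0.45                    0.00

mt <- mantel_env_screen(asm$bnti_detail, ds$env, n_perm = 999, seed = 42)
mt[mt$variable == "gradient", ]
#>   variable     r     p n_pairs
#>   gradient 0.863 0.002      66
```

55 % of all sample pairs — and 100 % of the pairs that straddle the
two environments — are classified as heterogeneous selection
(βNTI ≥ 2): phylogenetic turnover between environments exceeds the
tip-shuffle null, exactly the planted signal. The within-environment
pairs, which share a niche optimum, fall to homogenising dispersal.
The Mantel screen finds βNTI strongly associated with the true
filtering gradient (r = 0.86, p = 0.002) and not with the inert noise
variables.

The numbered drivers under `analysis/` run the same chain over all
three regimes and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # datasets + ground truth
Rscript analysis/02_partition_diversity.R
Rscript analysis/03_niche_breadth.R
Rscript analysis/04_assembly.R
Rscript analysis/05_network.R
Rscript analysis/06_mantel.R
```

For example `analysis/04_assembly.R` prints, per regime, the process
fractions and the recovery of the planted truth:

```text
neutral               heterogeneous_selection 0.03  homogeneous_selection 0.00  dispersal_limitation 0.00  homogenizing_dispersal 0.97  undominated 0.00
selection             heterogeneous_selection 0.55  ... cross-environment pairs heterogeneous-selection: 100%
dispersal_limitation  dispersal_limitation 0.55  ... between-pool pairs dispersal-limitation: 100%
```

## Package layout

```
R/                  implementation (io, partition/diversity, niche
                    breadth, assembly null models, networks, Mantel,
                    simulator, pipeline)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R  headline-number regeneration
tests/testthat/     unit, property and end-to-end validation suites
vignettes/          methods vignette: models, conventions, generator
                    design, limitations
```
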