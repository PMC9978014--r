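---
title: "Inferring community assembly processes from OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commassembly)
```

## The inference chain

`commassembly` takes three inputs — an OTU count table (samples ×
taxa), a rooted phylogeny with branch lengths whose tips are the OTU
ids, and a per-sample environmental table — and runs the chain of
community-ecology analyses used to ask *how* a microbial community is
assembled:

1. **Abundant/rare partition.** An OTU is abundant when its mean
   relative abundance is ≥ 0.01 % (`classify_abundance()`, threshold
   `1e-4`, boundary inclusive). All later stages can be run per
   abundance class, because abundant and rare subcommunities routinely
   show different assembly regimes.
2. **Diversity.** Observed richness, Shannon *H* (natural log), Pielou
   *J* = *H*/ln *S*, Chao1 and ACE per sample (`alpha_diversity()`),
   group comparison by one-way ANOVA with Tukey letters
   (`compare_groups()`), and Bray–Curtis PCoA (`pcoa_bray()`).
3. **Niche breadth.** Levins' *B* per OTU with a count-preserving
   permutation null that classifies OTUs as habitat generalists,
   specialists or neutral (`classify_specialists()`).
4. **Assembly processes.** βMNTD/βNTI (phylogenetic null model) and
   Raup–Crick on Bray–Curtis (RC~Bray~), combined into the five-way
   process classification (`assembly_processes()`).
5. **Co-occurrence networks.** Prevalence-filtered all-pairs Spearman
   networks with the usual topology summary (`build_network()`,
   `topology()`).
6. **Environmental association.** Mantel tests (Spearman) of the βNTI
   matrix against single-variable Euclidean environmental distances
   (`mantel_env_screen()`).

`run_all()` sequences all stages over one configuration and writes a
deterministic `report.json`.

## Models and conventions

### Levins' niche breadth

For OTU *j* with relative abundance *P~ij~* in community *i*, the
across-community distribution is *q~ij~* = *P~ij~* / Σ~i~ *P~ij~* and

$$B_j = \frac{1}{\sum_{i=1}^{N} q_{ij}^2}.$$

Only under this normalisation is *B* bounded in [1, *N*] — 1 for an
OTU confined to one community, *N* for a perfectly even one — which is
how Levins (1968) defined the index; formulations that square the raw
proportions lose the bound. The community summary *B~m~* is the
unweighted mean of *B* with a bootstrap standard deviation over 100
resamples of the OTU set.

The generalist/specialist test compares observed *B* to a null in
which the count matrix is randomised while preserving *every row and
column total* (a quasiswap on integer counts, 1000 permutations, 95 %
two-sided envelope by default). Matrices whose incidence contains
fewer than two checkerboard 2×2 submatrices cannot be mixed by swaps —
this genuinely happens when every abundant OTU occurs in every sample
— and then the package falls back, with a warning, to a
`row_proportion` null that redistributes each sample's total
multinomially at metacommunity proportions.

### βMNTD, βNTI and the five-process scheme

Between samples *A* and *B*, with *p* the within-sample relative
abundances over the OTUs present and *d* the patristic distance,

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_{j \in A} p_{jA}
\min_{k \in B} d_{jk} + \sum_{j \in B} p_{jB} \min_{k \in A}
d_{jk}\Big],$$

the abundance-weighted form (the default of the Stegen framework that
this scheme comes from). βNTI standardises the observed βMNTD against
999 tip-label shuffles of the whole phylogeny:
βNTI = (obs − mean~null~)/sd~null~. RC~Bray~ ranks the observed
Bray–Curtis dissimilarity within 999 null draws that preserve each
sample's richness and total abundance, drawing species by occurrence
frequency and individuals by metacommunity relative abundance, and is
rescaled to [−1, 1].

Pairs are classified: βNTI ≥ 2 heterogeneous selection, βNTI ≤ −2
homogeneous selection; otherwise RC~Bray~ > 0.95 dispersal limitation,
RC~Bray~ < −0.95 homogenising dispersal, |RC~Bray~| ≤ 0.95
undominated. Boundaries follow the conventional printed thresholds
(|βNTI| ≥ 2 deterministic; RC strictly beyond ±0.95), so RC ties at
exactly ±0.95 stay undominated. Pairs whose null βMNTD has zero
spread (possible on degenerate star-like trees) get an undefined βNTI
and are excluded from the fractions, with the exclusion counted.

### Networks

Edges require |Spearman r| > 0.8 **and** p < 0.01 (both strict; raw
p by default, Benjamini–Hochberg as an option) after a prevalence
filter keeping OTUs present in ≥ ⌈2/3 · n⌉ samples. Correlations are
computed on counts — Spearman is rank-based, so this differs from
using proportions only when sequencing depths differ, and an option
switches to relative abundances. Topology is computed on the
unweighted graph: AD = 2E/V, mean local clustering with degree-<2
nodes contributing 0, mean shortest path within the largest connected
component (disconnected graphs have no global path length; the
component coverage is reported), density 2E/(V(V−1)). Modularity uses
Louvain, which depends on vertex order; the package reruns it (20
restarts by default) under seeded vertex permutations and reports
mean ± sd plus the best partition — the same reason desktop network
tools report modularity with a spread.

### Mantel tests

The Mantel statistic is the Spearman correlation of the lower
triangles; significance comes from jointly permuting rows and columns
of the second matrix, with a two-sided p =
(1 + #{|r~null~| ≥ |r~obs~|})/(n~perm~ + 1). βNTI matrices are not
metric distances; the test is applied to them as is conventional in
this literature, and should be read as a permutation association test,
not as an analysis of a distance geometry. Samples with missing
environmental values are dropped from both matrices
(pairwise-complete); nothing is imputed.

### Other numerical choices

* **Chao1** uses the classic estimator S~obs~ + F₁²/(2F₂), switching
  to the bias-corrected S~obs~ + F₁(F₁−1)/2 only when F₂ = 0; ACE uses
  the standard abundance-based coverage estimator with rare cutoff 10.
* **PCoA** clips negative Bray–Curtis eigenvalues to zero for the
  explained-variance shares (the count is reported) and canonicalises
  each axis so its largest-magnitude score is positive.
* **Tukey letters** are the maximal cliques of the
  "not-significantly-different" graph at α = 0.05, the standard
  compact letter display.
* Sample and OTU ids match exactly and case-sensitively; silent
  case-folding would hide upstream bookkeeping errors.
* All stochastic stages take explicit seeds; the pipeline derives
  per-component seeds from one master seed and echoes them into its
  report.

## The synthetic-data generator

Because the package is validated without any sequencing data, the
generator must produce communities whose assembly regime is *known*:

* **Abundance structure.** Metacommunity weights follow a
  core–satellite mixture: 40 % of the 300-OTU pool is a log-normal
  core (sdlog 1.5) holding essentially all reads; the remainder is a
  satellite tail 4 × 10⁻³ below it (sdlog 1). A single log-normal
  cannot, at a 300-OTU pool, make rare OTUs the majority of observed
  richness without concentrating most reads in one or two taxa — an
  evenness real communities do not show, and one that destroys the
  power of abundance-weighted βMNTD because the tip-shuffle null sd
  explodes when only a couple of taxa carry weight. The mixture is the
  classic empirical decomposition of species-abundance distributions
  and delivers both properties: at the defaults (12 samples, depth
  50 000 — a typical per-sample 16S depth), rare OTUs are ≈ 56–62 % of
  observed richness and well under 1 % of reads.
* **Phylogeny and traits.** A pure-birth tree rescaled to depth 1; one
  niche trait evolved by Brownian motion on a depth-rescaled copy of
  the tree (exponent `trait_delta = 0.3`, a Pagel's-δ-style early
  burst). Plain Brownian motion frequently produces between-clade
  trait convergence, in which case two environments select
  similar-trait but phylogenetically scattered taxa and βNTI —
  correctly — finds no phylogenetic turnover signal; concentrating
  divergence in the deep branches makes niche optima clade-cohesive,
  which is what "phylogenetically conserved niches" must mean for a
  phylogenetic null model to be able to see selection at all.
* **Regimes.** *Neutral*: every sample draws multinomially from the
  metacommunity. *Selection*: two sample halves at niche optima ±1 on
  the z-scored trait scale with a Gaussian filter of width σ = 0.5 —
  strong filtering, each environment admitting roughly one trait
  standard deviation. *Dispersal limitation*: OTUs are randomly
  assigned to two disjoint pools, samples draw from one pool each;
  random assignment keeps pools phylogenetically unstructured, so the
  planted signal is compositional (RC~Bray~ → +1), not phylogenetic.
* **Environment.** The true gradient plus independent standard-normal
  noise variables, so Mantel recovery and type-I behaviour can both be
  checked.

What the generator does **not** emulate: real sequencing noise (PCR
and copy-number bias, chimeras), taxon-specific detection efficiency,
more than one niche axis, gradual (non-binary) gradients, and the
10-fold larger richness of real soil communities. Passing the
validation suite therefore shows the *inference chain* is correct and
calibrated on communities with known truth; it does not certify
recovery rates on any particular real dataset.

## Problem sizes and replicate counts

Function defaults follow the conventional 999 null draws and 1000
permutations. The validation suite and the acceptance script run the
null models at 199 replicates and the pipeline default is
`n_null = 199`: βNTI and RC are means/quantiles whose Monte-Carlo
error at 199 draws is already far below the ±2 and ±0.95 decision
thresholds, and this keeps the full validation (three regimes × 66
sample pairs, plus permutation nulls) comfortably fast on one CPU.
The analysis scripts under `analysis/` use the full 999.

## Known limitations

* βNTI detects selection only insofar as niches are phylogenetically
  conserved at the scale of the realised communities; the generator's
  `trait_delta = 1` setting demonstrates the failure mode.
* RC~Bray~ null draws are shared per sample within a replicate (each
  replicate draws one null community per sample and compares all
  pairs). Per-pair marginal null distributions are identical to fully
  independent draws; only across-pair correlation within a replicate
  is introduced, which the per-pair RC quantile never uses.
* The quasiswap null requires checkerboard structure; fully saturated
  incidence submatrices (all abundant taxa everywhere) silently carry
  less information about generalism than sparse ones, and the
  row-proportion fallback tests a weaker null.
* The network stage is a correlation screen, not an interaction model;
  compositionality-aware inference (SparCC-style) is out of scope.
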