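---
title: "Placing whole genome duplications: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing whole genome duplications: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wgdplacer` implements the two complementary lines of evidence that
plant phylogenomics uses to detect and place ancient whole genome
duplications (WGDs): the distribution of synonymous divergence (Ks)
among within-species paralog pairs, whose modes mark bursts of
duplication, and gene-tree/species-tree reconciliation, which locates
the species-tree branch on which a burst of shared duplications falls.
Because real transcriptome compendia are far beyond desk scale, the
package ships a first-class synthetic-data module that generates gene
families, codon sequences and GO tables with *known* planted signal,
so every stage can be validated end to end.

## 1. The synthetic generator: what it emulates

`make_ladder_tree(n_tips, depth)` builds the fully pectinate
(caterpillar) ultrametric species tree that gene-tree sorting methods
require, with evenly spaced divergence times and the deepest tip
(`t1`) as outgroup. Time units are arbitrary; we speak of MY below.

`simulate_gene_family()` runs a linear birth–death process forward
along the tree: every gene lineage duplicates at rate $\lambda$ and
dies at rate $\mu$ (both per gene per MY), lineages follow both
daughters at speciations, and at each planted `wgd_event()` every
lineage alive at that instant duplicates independently with
probability equal to the event's *retention rate*. Of the two readings
of a "20% retention rate" (duplicate retained at the event vs. the
extra copy surviving to the present) we implement retention **at the
event**: it is the simplest generative reading, it keeps the planted
signal interpretable (the fraction of families carrying a WGD
duplicate equals the retention rate when $\lambda=\mu=0$), and any
post-WGD decay is already carried by the background $\mu$. The
mechanism is configurable through the event's `retention_rate` and the
background rates.

Duplication nodes in the output gene tree are labelled by origin
(`D:background` vs. `D:<wgd id>`), which gives the tests and
benchmarks their ground truth. `simulate_family_set()` adds the
conditioning used throughout the inference side: at least one
surviving copy in the outgroup, at least one in some other taxon, and
no taxon above a 100-copy cap. The default root copy number is 1; a
different root prior can be emulated by `root_copies`.

**Benchmark conditions.** The synthetic study conditions used by the
acceptance benchmarks are fixed once: a 6-taxon ladder of depth
300 MY, $\lambda=\mu=0.002$ per gene per MY (a typical plant nuclear
gene-family turnover scale, and the value the end-to-end recovery
benchmark prescribes), one WGD at the midpoint of the branch leading
to node `N4`, retention 0.2, 2,000 conditioned families per empirical
replicate. These are study conditions, not tuning knobs.

### Codon sequences

`evolve_codon_sequences()` evolves in-frame codon sequences down the
gene tree under a mutation–selection process: each nucleotide position
mutates at rate $r$ (the `syn_rate` parameter), the target is uniform
among the non-stop single-nucleotide neighbours of the current codon,
synonymous changes are always accepted, and nonsynonymous changes are
accepted with probability $\omega$ (default 0.2, a realistic
genome-wide dN/dS for plant nuclear genes). Because the NG86 site
convention used by the estimator normalises per position by the same
non-stop neighbour sets, synonymous substitutions accrue at exactly
$r$ per synonymous site, so a pair of genes whose lineages split $T$
MY ago has expected Ks $\approx 2Tr$. Empirically the NG86+JC estimate
of the simulated process is accurate to about 1% for $2Tr \le 1$;
beyond Ks $\approx 2$ multiple hits dominate and the estimator flags
saturation rather than pretending accuracy. There are no indels, no
across-site rate heterogeneity and no codon-usage bias — so a passing
test says the *pipeline* recovers planted peaks, not that real
transcriptome alignments are this clean.

### GO tables

`plant_go_bias()` assigns one GO Slim category per gene: genes that
descend from a named WGD duplication draw the biased categories with
probability multiplied by the enrichment factor (renormalised);
everything else draws uniformly. Factor 1 is the null fixture used to
calibrate the enrichment caller.

## 2. Ks toolkit

`estimate_ks()` is Nei–Gojobori (1986) counting with Jukes–Cantor
correction per site class, pathway-averaged for codons differing at
more than one position, with stop-codon pathways excluded. This is a
deliberate divergence from codeml-style ML counting: it is
deterministic, dependency-free, and adequate for peak-*position*
recovery, which is all the downstream analysis needs. Saturated pairs
(JC log argument $\le 0$) return `NA` and are excluded by the analysis
window.

`build_paralog_distribution()` scores all within-family, within-species
pairs and keeps Ks in the window $[0.01, 5]$ (default): the lower
bound suppresses alleles and assembly artefacts, the upper bound
discards saturated noise. Node weighting (`dedup = TRUE`) follows the
usual correction for non-independent pairs: average-linkage clustering
of a family's genes on Ks, one unit of weight per inferred duplication
node split among the pairs joined there. It is off by default and both
modes are tested.

`fit_mixture()` fits Gaussian mixtures with k = 1..4 by EM on raw Ks
(not log-transformed) and selects k by minimum AIC, ties to the
smaller k. Two numerical choices matter and are deliberate:

* **Initialisation.** The default is a single deterministic
  quantile-spread initialisation. Aggressive random restarts let EM
  find degenerate narrow-spike components which plain AIC rewards;
  with the deterministic start, unimodal data select k = 1 in ≥ 95% of
  seeds while well-separated bimodal data still recover both
  components to within 0.05. Random restarts remain available via
  `n_restarts`.
* **Peak evidence.** A multi-component model counts as evidence of a
  peak only when it beats k = 1 by more than 2 AIC units
  (`delta_aic`); the underlying AIC comparison convention does not fix
  a margin, and ΔAIC > 2 is the customary "positive evidence" line.

The EM asserts a non-decreasing log-likelihood at every iteration, the
SD floor is $10^{-4}\,\mathrm{sd}(x)$, convergence is a relative
log-likelihood change below $10^{-7}$, and a k whose fits all fail is
excluded from selection.

`sizer_scan()` is a SiZer-style significant-slope map: the density
derivative is estimated with a Gaussian kernel over log-spaced
bandwidths (default 11 in $[0.05, 1]$ Ks units) and classified
increasing/decreasing/flat by pointwise normal CIs at level
$1-\alpha$ (default $\alpha = 0.05$), with an effective-sample-size
cutoff of 5. Pointwise means pointwise: single cells go significant at
the nominal rate even under a flat truth. The boundary of a bounded
support genuinely tilts the *smoothed* density (for Uniform(0, 3) and
bandwidth h the expected derivative at x is
$(\varphi(x/h) - \varphi((3-x)/h))/(3h)$, positive well inside the
support once x is within a few h of 0), so "increasing" calls near a
boundary are correct statements about the smoothed curve, not false
positives. Calibration is therefore assessed as a rate over
replicates on a grid at least four bandwidths from the support
boundary.

`ortholog_ks()` takes only families with exactly one gene in each
species (no best-hit rescue; ambiguous families are excluded
entirely), and summarises by the kernel-density mode.
`rate_correct_peak()` applies the relative-rate trio decomposition
$d_F = (d_{FS} + d_{FO} - d_{SO})/2$, placing the focal–sister
speciation at $2 d_F$ on the focal paralog scale; a paralog peak older
than that is a shared-WGD candidate. Negative $d_F$ flags the trio
inconsistent and yields no verdict. `flag_saturation()` marks mixture
components with mean Ks strictly above 2 as possible saturation
peaks requiring reconciliation-based corroboration.

## 3. Duplication mapping (gene-tree sorting)

`lca_map()` is standard soft-parsimony LCA reconciliation: each
gene-tree node maps to the species-tree LCA of its descendant species;
a node is a duplication iff it maps where one of its children maps.
`duplication_profile()` aggregates per species-tree node and **per
gene tree**: `n_mapped` counts gene trees with at least one internal
node mapped to the node, `n_duplicated` those where such a node is a
duplication. Counting trees rather than subtree nodes makes the
statistic directly interpretable (with $\lambda=\mu=0$ and retention
0.2, the proportion at the planted node is 0.2) and matches the
"proportion of gene trees duplicated at a node" reading of the
statistic. Within-species expansions (duplications mapping to tips)
are tallied separately and excluded.

Rooting in `filter_and_root()` uses the outgroup genes; when they are
not monophyletic the tree is rooted on the largest outgroup-only clade
and a warning is logged. Polytomies are resolved deterministically.
The occupancy filter (default 45% of species present) mirrors the
usual gene-tree inclusion rule.

## 4. Birth–death inference and the WGD test

`bd_transition_matrix()` implements the classical Kendall
single-ancestor law — $P(0)=\alpha$,
$P(n)=(1-\alpha)(1-\beta)\beta^{n-1}$ with the standard
$\alpha,\beta$ and the explicit critical-case limit
$\alpha=\beta=\lambda t/(1+\lambda t)$ — and builds multi-ancestor
rows by iterated convolution. The state space is truncated at 200
(twice the 100-copy family cap); `estimate_rates()` adapts the
truncation to the data (at least 40, at most 200) and mass
conservation is checked. `bd_loglik()` is the pruning algorithm over
family counts with a geometric root-size prior and `oneInBothClades`
conditioning (at least one surviving copy in each root-child clade —
exactly the ascertainment imposed by the conditioning filter when the
outgroup is a root child).

The geometric-mean-of-family-size root prior is the protocol default,
but it is a *model* choice: on data whose families genuinely start
from one root copy it is badly misspecified and drags
$\hat\lambda$ down and $\hat\mu$ up several-fold. The scenario
configuration therefore exposes `root_prior_mean`, the demo scenario
sets it to 1 (matching its generator), and the benchmarks estimate
with the matched prior. Rates are estimated on ten random subsets of
500 families by Nelder–Mead on log-rates; per-subset MLEs, their mean
and SD are reported. $\lambda$ and $\mu$ are not constrained equal.

`build_null_and_positive()` simulates the protocol pools: three null
regimes of 1,000 trees at the ML, half-ML and 3×-ML rates, and 3,000
positive trees (split evenly across the same regimes) with the
candidate WGD at the branch midpoint and 20% retention.
`fisher_compare()` is a two-sided Fisher's exact test on the
(duplicated, not) × (empirical, simulated) table with the direction
reported; sidedness is not fixed by the source protocol, so the
decision rule consumes direction plus two-sided p. No multiple-testing
correction is applied across nodes by default.

**Which positive profile to compare against.** The pooled null is kept
as the reference for the null test — pooling across rate regimes is
exactly its robustness job. Pooling the *positive* regimes, however,
is systematically biased: at 3× the ML rates more gene lineages are
alive at the WGD instant, each retaining independently, so the pooled
positive proportion exceeds what data generated at the ML rates can
show, and a genuinely planted WGD gets downgraded to "partial" once
sample sizes give Fisher the power to see a few percentage points.
The decision rule therefore tests against the ML-regime positive
(`positive_ml`); the pooled positive and all per-regime profiles are
emitted as diagnostics. `call_wgd()` then returns **supported**
(above the null, not significantly below the positive), **partial**
(above the null but significantly below the positive — the elevated
signal that falls short of a planted-WGD expectation), or
**unsupported**.

## 5. Retention and GO bias

`assign_paralogs()` assigns a pair to a mixture component only when
both criteria hold: Ks within ±1 fitted SD of the component mean, and
the component having the pair's maximum posterior responsibility; ties
are left unassigned. Assignment is monotone in the window width.
`retention_rate()` counts *genes* (distinct members of assigned
pairs) against the predicted-gene total; both gene and pair counts are
emitted. Note the two natural denominators disagree: at the family
level, with $\lambda=\mu=0$ the fraction of families carrying a WGD
duplicate equals the retention rate, which is the quantity the
generative benchmark checks.

`go_bias()` is a chi-squared goodness-of-fit of the paralogs' GO Slim
tallies against background proportions, with standardized (Pearson)
residuals $(O-E)/\sqrt{E}$ called over/under at ±2 — the residual
convention of the enrichment literature this analysis follows;
multi-label genes contribute one tally per annotation.
`cross_event_matrix()` orders events by component median Ks and
summarises per-category convergence as the fraction of event pairs
sharing a call.

## 6. Problem sizes, calibration and limitations

The suite's benchmark sizes are chosen as the smallest that give the
statistics their nominal behaviour: 2,000-family empirical replicates
(binomial SE on a 0.2 proportion ≈ 0.009), protocol-size simulation
pools generated once per analysis and shared across the 20 empirical
replicates, 500+ retained pairs for sequence-level peak recovery
(fitted component mean within ±15% of $2tr$), 1,000 replicates for
slope-scan calibration and 10,000 tables for enrichment calibration
(expected over/under rate $2\,P(|Z|>2) \approx 4.6\%$).

Known limitations: the Ks estimator inherits NG86's saturation
behaviour above Ks ≈ 2 (hence the saturation flags and the analysis
window); the sequence simulator omits indels, rate heterogeneity and
codon-usage bias; reconciliation assumes rooted, ladder-compatible
species trees and up to 30 species (bitmask encoding); the
birth–death model treats rates as constant across families and
branches; and the GO layer is flat GO Slim with no graph propagation.
Passing the synthetic benchmarks demonstrates internal correctness of
the machinery under the stated generative model, not robustness to
assembly artefacts, alignment error or heterotachy in real
transcriptomes.

## 7. A worked run

```{r demo}
library(wgdplacer)
man <- run_pipeline(demo_scenario(seed = 11L), out_dir = "demo_out")
man$results$bdtest$calls          # per-node WGD verdicts
man$results$retention$rate        # percent of genes in duplicate
head(man$results$retention$enrichment)
```

The same stages can be driven individually; see `?simulate_family_set`,
`?fit_mixture`, `?duplication_profile`, `?call_wgd` and
`?benchmark_recovery`.
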