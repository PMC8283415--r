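---
title: "Dissecting abundant and rare subcommunity assembly along a stress gradient"
author: "microassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting abundant and rare subcommunity assembly along a stress gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microassembly)
```

## The scientific question

Soil bacterial communities exposed to a pollutant gradient — here modelled
on pyrene-spiked microcosms with doses of 0, 1, 10, 100 and 500 mg per kg
dry soil — reorganise in ways that differ sharply between their *abundant*
and *rare* members. `microassembly` implements the full inference chain
used to dissect that reorganisation from a rarefied OTU count table, a
sample metadata table and a rooted phylogeny:

1. partition OTUs into abundant / moderate / rare subcommunities;
2. quantify diversity, Bray–Curtis turnover and a Shannon-based
   resistance index;
3. measure Levins' niche breadth per OTU and per subcommunity;
4. fit the Sloan neutral community model;
5. classify pairwise assembly processes with βNTI and RC~Bray~ null
   models;
6. build Spearman co-occurrence networks with a random-matrix-theory
   threshold.

Every stage can be exercised against simulators with known ground truth,
so the statistical machinery is testable without any sequencing data.

## Data model

An `OtuExperiment` extends `SummarizedExperiment`: one integer `counts`
assay with OTUs as rows and samples as columns, sample metadata
(`treatment`, `dose`, `replicate`) in `colData`, optional taxonomy in
`rowData`. Identifiers must be unique and counts non-negative integers;
validity is enforced at construction. Phylogenies are `ape::phylo`
objects whose tip labels name OTUs. Rarefaction
(`rarefyTable`) subsamples without replacement (multivariate
hypergeometric) to a common depth with an explicit seed argument — never
global RNG state — and keeps all-zero OTUs so identifier spaces stay
aligned across treatments; downstream operations ignore all-zero rows.

## Partitioning rules

The cutoffs are the fixed conventions of the abundant/rare literature:
an OTU is **abundant** in a treatment when its relative abundance reaches
1% (`abundantCut = 0.01`) in *at least one sample* of the treatment;
**rare** when its *treatment-mean* relative abundance is below 0.01%
(`rareCut = 1e-4`); **absent** with zero counts throughout; **moderate**
otherwise. The mixed per-sample / per-treatment phrasing of the
convention leaves a genuinely open corner — a spiky OTU can satisfy both
the abundant and the rare rule — which we resolve by giving the abundant
rule precedence: a taxon that ever dominates a sample is not rare. The
moderate class is defined by exclusion, which keeps the three classes
disjoint and exhaustive over present OTUs by construction. A pooled
"global" classification is available behind a flag for sensitivity
analysis.

## Diversity and resistance

Shannon (natural log) and Gini–Simpson indices are delegated to
`vegan::diversity`; Bray–Curtis to `vegan::vegdist`. The resistance of a
perturbed community relative to the control is

$$RS = 1 - \frac{2\,|D_0|}{C_0 + |D_0|}, \qquad D_0 = C_0 - P_0,$$

with $C_0$ the control-mean Shannon and $P_0$ the perturbed replicate's
Shannon. This bounded-difference form (the Orwin–Wardle index) equals 1
exactly when the perturbed value matches the control, falls to 0 at total
loss, is strictly decreasing in $|D_0|$, and lies in $(-1, 1]$. The
source convention for this statistic names the index without printing a
formula; adopting this form is a documented package assumption.
Per-replicate resistance is computed against the control-treatment mean
and averaged within treatment.

## Levins' niche breadth

For OTU $i$ with proportion $P_{ij}$ of its abundance in resource state
$j$ of $r$ states, $B_i = 1 / \sum_j P_{ij}^2$, ranging from 1 (perfect
specialist) to $r$ (perfect generalist). The default resource state is
the individual sample; a treatment-level aggregation is available. OTUs
absent from the whole scope are excluded from the community mean rather
than contributing $B = 0$, because breadth is undefined for an absent
taxon. Which sample subsets define the states of a per-treatment width is
not fixed by convention; the package computes widths over whichever
sample scope the caller passes, and the per-treatment width used in our
examples is the breadth over that treatment's samples.

## Sloan neutral community model

Under drift with immigration probability $m$ into local communities of
$N$ individuals, the stationary relative abundance of a taxon with
metacommunity frequency $p$ is $\mathrm{Beta}(Nmp,\; Nm(1-p))$, so the
expected occurrence frequency across samples is
$\hat f(p) = 1 - \mathrm{BetaCDF}(d;\, Nmp,\, Nm(1-p))$ for detection
limit $d$. `fitNeutralModel` estimates $m$ by bounded one-dimensional
least squares of observed frequencies on $\hat f$ ($m \in (10^{-6}, 1]$),
fixes $N$ at the mean sample depth rather than co-estimating it (the
model is effectively one-parameter given $N$), reports
$R^2 = 1 - SSE/SST$ about the mean observed frequency (negative values
are possible for anti-neutral data and are not clamped), and partitions
OTUs against Wilson 95% binomial bands on $\hat f$ at $n =$ number of
samples.

**Detection limit.** Presence is observed as "at least one read", an
event with probability $1 - (1 - x)^N$ given true abundance $x$. That
soft kernel crosses one half at $x = 1 - 2^{-1/N} \approx \ln 2 / N$, so
the default $d$ is this continuity-corrected value rather than the sharp
$1/N$. At the depths of real amplicon data the two are indistinguishable,
but at modest simulated depths ($N = 10^3$) the sharp convention
systematically overestimates $m$ against an exact drift simulation
(+35% at $m = 0.1$ in our calibration runs vs +5% with the corrected
default). `d` remains an argument for users who want the sharp
convention.

## Null models for assembly processes

β-mean-nearest-taxon distance is abundance-weighted:

$$\beta MNTD_{kl} = \tfrac12\Big[\sum_{i\in k} f_{ik}\,\min_{j\in l} D_{ij}
 + \sum_{j\in l} f_{jl}\,\min_{i\in k} D_{ij}\Big]$$

with $D$ the patristic distance; a taxon present in both communities is
its own nearest neighbour. βNTI standardises the observed value against
`nNull` (default 999) shuffles of tip labels across the whole tree — the
regional pool is all OTUs in the scope. The permutation loop runs in
compiled code: the tip distance matrix is computed once and nulls only
permute indices, which keeps 30 samples × 2,000 OTUs × 999 nulls within
minutes on one CPU. Pairs whose null distribution is degenerate (e.g. a
star phylogeny, where every shuffle is identical) are reported `NA`
rather than as a spurious z-score; the zero-variance test is relative at
square-root machine precision because the null variance is accumulated in
floating point.

RC~Bray~ builds, per sample pair, `nNull` null pairs that preserve each
sample's richness and total abundance: species are drawn without
replacement with probability proportional to occurrence frequency (via
exponential race keys, distributionally identical to successive weighted
sampling), receive one individual each, and the remaining individuals are
assigned multinomially by regional mean relative abundance. The observed
Bray–Curtis value is ranked in the null distribution with half-weight for
ties and rescaled to $[-1, 1]$. The regional pool defaults to the table
being analysed but can be supplied explicitly, which is what one should
do when analysing a treatment or subcommunity subset of a larger
experiment.

Process labels follow the fixed two-stage rules: βNTI $< -2$ homogeneous
selection, $> 2$ variable selection; otherwise RC $< -0.95$ homogenizing
dispersal, RC $> 0.95$ dispersal limitation, $|RC| < 0.95$ undominated.
Exact boundary hits — probability-zero in floating point, but made
deterministic — fall to the selection / dispersal side. Fractions can be
aggregated over within-treatment pairs, optionally folding
control-vs-treatment pairs into the perturbed treatment's group, the
default grouping for dose-response designs.

## Co-occurrence networks

Spearman correlations are computed after a prevalence filter (default:
present in ≥ 1/3 of samples, the "majority rule"); constant vectors give
`NA`. The threshold scan zeroes $|\rho| < t$ for
$t = 0.30, 0.31, \ldots, 0.99$, unfolds the eigenvalue spectrum with a
degree-5 polynomial fit to the cumulative spectral function, and tests
the nearest-neighbour spacing distribution (20 bins on $[0,3]$) against
the Poisson law by chi-square; the smallest accepted $t$ ($p > 0.05$) is
returned. Dense correlated noise shows Wigner–Dyson level repulsion;
once the retained structure is sparse and modular the spacings become
Poisson. Unfolding parameters are free in the RMT-threshold literature;
the values here were chosen for stability at matrix sizes of order
$10^2$–$10^3$. When no cutoff is accepted the scan falls back to
$|\rho| \ge 0.8$ with a warning and a flag on the return value. On
planted-block fixtures the accepted cutoff sits between the background
correlation and the block correlation — a cutoff above the within-block
level would delete the very structure the network is meant to capture,
so we test for noise/structure separation rather than for an absolute
threshold value.

Edges keep their signed correlation; an abundant–rare mode restricts
edges to pairs linking one abundant and one rare OTU. Betweenness is
reported raw (so the star-centre closed form $(n-1)(n-2)/2$ holds) with a
normalised column alongside; local clustering is 0 for nodes with fewer
than two neighbours. The scale-free statistic is the $R^2$ of the
log–log least-squares fit of degree frequencies, the convention of
co-occurrence network studies.

## Simulators and what they do (and do not) emulate

The generators share a lognormal metacommunity (`meanlog 0`, `sdlog 2` —
a few dominant and very many rare OTUs) and a Yule phylogeny rescaled to
unit depth with a Brownian trait as each OTU's environmental optimum, so
selection is phylogenetically structured and therefore visible to
tip-shuffling null models.

* `simulateNeutral` evolves each sample independently by
  death–replacement (immigration probability `m`). Burn-in is
  `max(10, 5/m) × depth` events: compositional variance relaxes at a rate
  of roughly $2m$ per generation, so a fixed short burn-in would leave
  small-`m` samples biased towards the metacommunity; at `m = 1` the
  samples reduce exactly to multinomial draws.
* `simulateGradient` samples each treatment multinomially with weights
  $w_i \propto \mathrm{meta}_i \exp(s \cdot \mathrm{dose}' \cdot z_i)$,
  where $z_i$ is the standardised trait and $\mathrm{dose}'$ the
  $\log(1+x)$-scaled dose normalised to $[0,1]$ so the top dose does not
  numerically annihilate the rare tail. `selectionStrength = 0` reduces
  to neutral metacommunity sampling.

Samples are independent draws: there is no spatial autocorrelation, so
*dispersal limitation in real data cannot be regenerated* — null-model
tests on these fixtures target calibration (type-I behaviour) and
selection detection, not the dispersal classes. Nor do the simulators
model PCR/sequencing error, copy-number variation or temporal dynamics;
passing tests therefore demonstrate the correctness and calibration of
the statistics, not that any particular field system obeys them.

`makeFixtures` materialises matched neutral + gradient fixtures at two
scales — "tiny" (50 OTUs, 4 treatments × 3 replicates, depth 1,000;
seconds to analyse end-to-end) and "paper" (2,000 OTUs, 5 treatments ×
6 replicates, depth 39,134) — as plain-text TSV/newick/JSON with the
generating parameters recorded as ground truth.

## Numerical choices and degenerate inputs

* Rarefaction requires every sample to reach the target depth and lists
  offenders; depth 0 is legal and yields an all-zero table.
* Relative abundance errors on all-zero samples; Bray–Curtis reports a
  pair of all-zero samples as `NA`.
* `classifyProcess` is total on finite inputs; `NA` statistics propagate
  to `NA` labels, which `processFractions` drops (fractions still sum
  to 1 over classified pairs).
* The NCM fit refuses data whose occurrence frequencies are all 0/1 with
  fewer than three distinct values — there is no information about `m`.
* Ties in Spearman ranks are mid-ranked; correlation p-values use the
  t approximation.
* All stochastic functions take explicit integer seeds and restore the
  caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite and the reproduction script run entirely on simulated
data sized for a desk machine: formula oracles in milliseconds;
brute-force graph/phylogeny equivalences at ≤ 12 nodes / 4 tips;
neutral-model recovery at 1,000 OTUs × 30 samples × depth 1,000 over 20
replicates; null-model calibration at 50 OTUs × 12–30 samples with 999
randomisations; and the full-chain script at 500 OTUs × 30 samples ×
depth 8,000. These sizes are the package's own choice of
simulation-study design: large enough for the asymptotics that the
statistics rely on, small enough to re-run routinely.

## Known limitations

* The resistance formula is an adopted convention (see above); studies
  using a different bounded index will not be numerically comparable.
* The Sloan fit treats OTUs as independent observations; phylogenetic
  or compositional correlation between OTUs is ignored, as in the
  original model.
* The fitted `m` estimates the Sloan-model immigration parameter; on
  data from an exact Moran process it absorbs the $m/(1-m)$ continuum
  correction, a ~10% upward shift at `m = 0.1` that vanishes for small
  `m` or large `N`.
* The RMT threshold is a heuristic: with few samples the Spearman noise
  floor is high and the NNSD test has limited power on small matrices
  (below ~200 OTUs the scan can accept thresholds that admit noise
  edges).
* RC~Bray~ calibration is exact only when the regional pool is supplied;
  re-estimating the pool from few samples shifts the null slightly.
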