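# microassembly

Tools for dissecting how **abundant** and **rare** bacterial
subcommunities assemble along an environmental stress gradient — the
inference chain used in soil-microcosm studies of pollutant dose effects
(e.g. pyrene at 0–500 mg kg⁻¹ dry soil) on 16S OTU tables.

From a rarefied OTU count table, per-sample metadata (treatment, dose,
replicate) and a rooted phylogeny, the package:

* **partitions** OTUs per treatment into abundant (relative abundance
  ≥ 1% in at least one sample), rare (treatment mean < 0.01%) and
  moderate classes, and tracks class transitions along the gradient;
* computes **α-diversity** (Shannon, Gini–Simpson), **Bray–Curtis**
  dissimilarity and a Shannon-based **resistance index**
  RS = 1 − 2|D₀|/(C₀ + |D₀|), where D₀ is the perturbed community's
  Shannon shortfall against the control mean C₀;
* measures **Levins' niche breadth** B = 1/ΣPⱼ² per OTU and mean niche
  width per (sub)community;
* fits the **Sloan neutral community model**
  f̂(p) = 1 − BetaCDF(d; Nmp, Nm(1−p)), estimating the immigration
  probability m by bounded least squares, with R², Nm and Wilson 95%
  bands partitioning OTUs into above/neutral/below;
* classifies pairwise **assembly processes** from abundance-weighted
  βMNTD/βNTI (tip-shuffling null, compiled kernel) and probabilistic
  **Raup–Crick** on Bray–Curtis: βNTI < −2 homogeneous selection,
  βNTI > 2 variable selection, then RC < −0.95 homogenizing dispersal,
  RC > 0.95 dispersal limitation, |RC| < 0.95 undominated;
* builds **Spearman co-occurrence networks** with a random-matrix-theory
  (eigenvalue spacing) threshold, per-node degree / betweenness /
  clustering, an abundant–rare edge mode and a power-law degree-fit R²;
* ships **simulators** (neutral drift with immigration; dose-responsive
  selection on a Brownian trait over a Yule phylogeny) so every stage is
  testable against known ground truth.

## Worked example

Simulate a three-dose gradient with phylogenetically structured
selection, then run the chain:

```r
library(microassembly)

cfg <- simulationConfig(nOtus = 300, nPerTreatment = 4,
                        treatments = data.frame(label = c("Control", "PYR10", "PYR500"),
                                                dose = c(0, 10, 500)),
                        depth = 5000, selectionStrength = 3, seed = 7)
phy <- simulatePhylogeny(cfg$nOtus, seed = cfg$seed + 7L)
sim <- simulateGradient(cfg, tree = phy$tree, traits = phy$traits)
soil <- sim$table

classifyAbundance(soil)
#> AbundanceClassification (abundant >= 0.01 in a sample, rare < 0.0001 treatment mean)
#>          class
#> treatment abundant moderate rare absent
#>   Control       22      222   26     30
#>   PYR10         18      191   33     58
#>   PYR500        19      107   35    139

treatmentResistance(soil)
#>   treatment        RS       RS_sd
#> 1     PYR10 0.8483006 0.001923187
#> 2    PYR500 0.6436395 0.001595231

fitNeutralModel(soil)
#> Sloan neutral community model fit (282 OTUs, 12 samples)
#>   m = 0.5213   N = 5000   Nm = 2606.5   R2 = 0.751
#>   partition: above 13.8%, neutral 75.5%, below 10.6%

asm <- assemblyProcesses(soil, phy$tree, nNull = 199, seed = 1)
processFractions(asm)
#>     group homogeneous_selection variable_selection homogenizing_dispersal
#> 1 Control                     0          0.0000000              0.5000000
#> 2   PYR10                     0          0.2727273              0.2727273
#> 3  PYR500                     0          0.7272727              0.2727273
#>   dispersal_limitation undominated n_pairs
#> 1            0.0000000         0.5       6
#> 2            0.4545455         0.0      22
#> 3            0.0000000         0.0      22
```

Reading the output: stress shrinks the community (139 OTUs absent at the
top dose), resistance declines with dose (0.85 → 0.64), and the fraction
of sample pairs shaped by variable selection grows from 0% in the
control to 73% at the top dose — the selection signal planted by the
simulator, recovered by the null models. A co-occurrence network follows
from `spearmanMatrix()`, `rmtThreshold()` and `buildNetwork()`; see the
vignette in `vignettes/community-assembly-methods.Rmd` for the models,
assumptions and tuning parameters.

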