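# spellclust

Spell-based phenotyping of longitudinal binary wheeze data.

## What problem this solves

Birth cohorts record current wheeze (yes/no) at a handful of harmonised
follow-up epochs from infancy to adolescence. Phenotypes derived directly
from those binary trajectories — typically by latent class analysis — are
internally heterogeneous, can assign children with *identical* wheeze
sequences to different phenotypes, and are fragile under missing data.
`spellclust` implements an alternative pipeline for epidemiologists working
with such cohorts:

1. **Spell variables.** Each complete sequence is transformed into six
   variables describing wheezing *spells* (maximal runs of consecutive
   wheezy epochs): age at first and last episode, number of wheezy epochs,
   longest spell, number of spells, and a categorical spell type
   (0 = none, 1 = single spell, 2 = intermittent).
2. **Mixed-data clustering.** Subjects are clustered with a deterministic
   partition-around-medoids (PAM) algorithm over a Gower-type dissimilarity

   d²(i,j) = Σₖ δᵢⱼₖ wₖ gₖ(i,j) / Σₖ δᵢⱼₖ wₖ,

   with variance-standardised squared differences for quantitative
   variables, simple mismatch for the spell type, and pairwise-deletion
   weighting (δ) for the never-wheezers' undefined ages. The number of
   clusters is selected from the knee of the PAM cost curve, with average
   silhouette reported alongside.
3. **Multiple-imputation consensus.** For cohorts with missing epochs, the
   pipeline runs inside each of M chained-equation imputations; labels are
   aligned across imputations by exact optimal relabelling and pooled into
   per-subject phenotype **membership probabilities**.
4. **Comparison arm and metrics.** A Bernoulli-mixture latent class model
   fitted by EM, plus adjusted Rand index, transition tables, aligned
   switching fractions, and within-cluster homogeneity profiles.
5. **Association stage.** Membership-weighted multinomial logistic
   regression (relative risk ratios with Wald 95% CIs; additive 0/1/2
   genotype coding supported) and DerSimonian–Laird random-effects pooling
   of per-cohort effects.

A seeded synthetic-cohort generator with a five-phenotype latent structure
(never / early-transient / late-onset / persistent / intermittent wheeze)
and configurable MCAR/MAR missingness makes every stage testable without
access to cohort data.

## Worked example

```r
library(spellclust)

co <- simulateCohort(2000, seed = 1)          # complete five-phenotype cohort
f  <- spellFeatures(co)                        # six spell variables
d  <- mixedDistance(f)                         # mixed-data dissimilarity
sel <- selectK(d, 2:8)                         # cost-knee cluster number
sel$kStar
#> [1] 5
fit <- sel$fits[["k5"]]
adjustedRand(clusterLabels(fit), truthLabels(co))
#> [1] 0.9259265
round(sel$diagnostics, 3)
#>   k totalCost avgSilhouette  elbow
#> 1 2   656.750         0.685  0.400
#> 2 3   443.476         0.728 -0.144
#> 3 4   259.280         0.812 -0.332
#> 4 5   108.757         0.915  0.666
#> 5 6    88.775         0.922 -0.039
#> 6 7    69.705         0.923 -0.016
#> 7 8    53.847         0.929  0.032
```

The knee of the cost curve (`elbow`) identifies the five generating
phenotypes; the ARI of 0.93 against the simulation truth says 2,000
subjects were recovered almost perfectly from their spell variables. Note
the average silhouette keeps creeping upward with k — on heavily duplicated
binary-sequence data it cannot locate the phenotype number, which is why
the knee is the default criterion (see the methods vignette).

With missing data, the consensus pipeline returns membership probabilities
instead of hard labels:

```r
amp  <- amputeSubjects(co, 0.3, 1:2, seed = 2) # 30% of subjects lose 1-2 epochs
cons <- consensusCluster(amp, M = 10, seed = 3, kRange = 2:8)
cons
#> ConsensusResult: n = 2000, k* = 5, mean certainty = 0.982
#>   selected k per imputation: 5 5 5 5 5 5 5 5 5 5
```

A mean certainty of 0.98 means subjects keep the same phenotype in nearly
every imputation. The membership matrix feeds the association stage
(`weightedMultinomial()`), and per-cohort effects pool with `dlMeta()`.

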