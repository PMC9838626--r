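---
title: "Spell-based phenotyping of longitudinal wheeze: models and methods"
author: "spellclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spell-based phenotyping of longitudinal wheeze: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spellclust)
```

## The problem

Birth cohorts record current wheeze as a yes/no answer at a handful of
harmonised follow-up windows ("epochs") from infancy to adolescence.
Data-driven phenotyping of these binary trajectories — most commonly by
latent class analysis (LCA) — has repeatedly produced class sets such as
never, early-transient, late-onset and persistent wheeze, but the classes
are internally heterogeneous, children with identical response sequences
can be allocated to different classes, and the allocation is sensitive to
missing data.

`spellclust` implements an alternative representation: each complete
binary sequence is first transformed into six *spell variables* that
describe the duration, timing, and recurrence structure of wheezing, and
clustering operates on those variables instead of the raw indicators. A
*spell* is a maximal run of consecutive epochs with reported wheeze. The
variables are:

| variable | type | definition |
|---|---|---|
| `first_age` | quantitative | encoded age of the first wheezy epoch (missing for never-wheezers) |
| `last_age` | quantitative | encoded age of the last wheezy epoch (missing for never-wheezers) |
| `n_records` | quantitative | number of wheezy epochs |
| `longest_spell` | quantitative | length of the longest spell |
| `n_spells` | quantitative | number of separate spells |
| `spell_type` | categorical | 0 = no wheeze, 1 = single spell, 2 = intermittent (two or more non-consecutive spells) |

Because the transformation is a pure function of the sequence, two
children with the same sequence always receive the same feature vector,
and any deterministic clustering of the features inherits that
consistency — the property `sequenceAudit()` certifies.

Epoch "ages" need a numeric encoding. The default is ordinal (1..T,
equal spacing); midpoints of the age ranges in years (0.75, 2.5, 4.5,
9, 16 for the default grid) are available via
`defaultEpochGrid("midpoint")` for sensitivity analyses. The source
studies pool age ranges per epoch and do not fix a numeric scale, so both
options are exposed and the choice is a user-visible parameter rather
than a hidden constant.

## The mixed-data dissimilarity

The six variables mix quantitative and categorical scales, and the two
age variables are undefined for never-wheezers. `mixedDistance()` uses a
Gower-type dissimilarity with variance standardisation:

$$d_{ij}^2 \;=\; \frac{\sum_k \delta_{ijk}\, w_k\, g_k(i,j)}
                       {\sum_k \delta_{ijk}\, w_k},$$

where $g_k = ((x_{ik}-x_{jk})/s_k)^2$ for quantitative variables,
$g_k = \mathbf{1}[x_{ik} \ne x_{jk}]$ for the categorical spell type, and
$\delta_{ijk} = 1$ only when variable $k$ is observed for both subjects
(pairwise deletion). This treats the never-wheezers' undefined onset and
offset ages natively — no sentinel age is fabricated, which would distort
the quantitative scale. Scales $s_k$ are the sample standard deviation
(n−1 denominator) by default, with range standardisation as an option;
weights default to 1. Two consequences worth knowing:

* a variable that is constant across the whole table carries no
  information and is excluded entirely (with a warning when it is a
  zero-variance quantitative variable), so dropping such a variable
  leaves the matrix unchanged;
* pairwise deletion means the triangle inequality is *not* guaranteed,
  which is why downstream clustering is medoid-based rather than
  centroid-based.

## Deterministic partition around medoids

`pamFit()` is a deterministic PAM: greedy BUILD initialisation (the first
medoid minimises total dissimilarity) followed by steepest-descent SWAP
until no single medoid/non-medoid exchange lowers the total cost, with
every tie broken to the lowest index. The fit is therefore a pure
function of the matrix, which matters for the consistency audit and for
reproducible multiple-imputation pipelines. The implementation agrees
with `cluster::pam` on the objective in testing; like all BUILD+SWAP
variants it is a local search, and the tests verify optimality against
exhaustive medoid enumeration on small instances, with a bounded excess
on the rare instances where steepest descent stops short.

### Choosing the number of clusters

`selectK()` fits all candidate k and reports total cost and average
silhouette per k. Two selection criteria are available.

The classical PAM companion — the average silhouette width — turns out to
be structurally unable to locate the phenotype number for this data type,
and the reason is worth recording. Five binary epochs admit only 32
sequences, so spell-feature space is heavily duplicated: thousands of
subjects sit on a few dozen distinct points. A cluster containing a
single duplicated pattern has zero within-cluster dissimilarity, and its
members score silhouette exactly 1 *no matter how close the neighbouring
clusters are*. Splitting off ever-smaller pattern groups therefore keeps
raising the average silhouette, which increases essentially monotonically
with k on such data.

The default criterion is instead the knee of the cost curve on the log
scale: $k^\* = \arg\max_k\,[\log W(k-1) - 2\log W(k) + \log W(k+1)]$,
where $W(k)$ is the PAM objective (the two flanking k are fitted as
needed). For a geometric cost decay this curvature is zero; it spikes
where the proportional gain of one more medoid collapses — which happens
exactly once every well-populated wheeze pattern has a medoid. On
synthetic five-phenotype cohorts (n = 2,000) the knee selects k = 5
across seeds while the silhouette criterion drifts to the top of the
candidate range; both criteria are reported in the diagnostics table so
the choice is auditable.

## The latent class comparison arm

`fitLCA()` fits the standard binary-data LCA — a k-component mixture of
independent Bernoulli indicators — by EM, with `nStarts = 20` random
initialisations, convergence at relative log-likelihood change below
`1e-8` (cap 1,000 iterations, flagged if hit), and item probabilities
clipped to $[10^{-6}, 1-10^{-6}]$. Internally the data are collapsed to
unique response patterns, so the cost scales with $2^T$ rather than n.
`lcaPosterior()` returns per-subject responsibilities and
maximum-posterior labels; identical sequences always receive identical
posterior rows, but a posterior *draw* does not — the mechanism by which
probabilistic allocation breaks sequence-to-phenotype consistency, and
one the audit can demonstrate.

A structural caveat: with k = 5 classes over T = 5 binary epochs the
model has $(k-1)+kT = 29$ free parameters against $2^5-1 = 31$ pattern
degrees of freedom. It is nearly saturated, and the likelihood has flat
directions: on synthetic cohorts of n = 20,000 the maximum-likelihood
solution routinely sits 0.05–0.2 away (in item-probability terms) from
the generating values even though its log-likelihood exceeds the one at
the truth by just the amount expected of an ML fit, and EM initialised
*at* the truth climbs to that same optimum. Parameter recovery to tight
tolerances at this depth of follow-up is a property the design cannot
deliver — for any implementation — and the package's tests document this
limit rather than hide it; EM correctness is instead established on
well-identified three-class configurations and via monotonicity and
seed-stability checks.

## Multiple imputation and consensus clustering

`imputeChained()` produces M completed datasets by chained equations:
missing indicators are initialised from observed per-epoch margins, then
each epoch's missing values are redrawn from a logistic regression on the
other epochs over several cycles (default 10), with an approximate
posterior draw of the coefficients so that imputations differ by more
than residual noise. Observed cells are never altered.

`consensusCluster()` runs the full spell pipeline (features → distance →
`selectK` → PAM) inside each imputation, pools the cluster number as the
modal selected k across imputations (ties to the smallest), refits each
imputation at k*, aligns labellings to the first imputation by optimal
relabelling (exact search over the $k \times k$ overlap table), and
reports each subject's membership probability in a phenotype as the
fraction of imputations placing it there. With complete data every
imputation is identical and the memberships are exactly 0/1; with M = 1
the result reduces to a single pipeline run. Spell features of a subject
depend only on its own sequence, so subjects with complete data keep
identical features in every imputation — the structural reason the
spell-based approach is robust to other subjects' missingness, and the
property the acceptance experiment quantifies.

## The association stage

`weightedMultinomial()` consumes the consensus membership matrix
directly: each subject contributes one fractional observation per
phenotype, weighted by its membership probability, to a multinomial
logit against a reference phenotype (algebraically identical to weighted
row expansion). The fit uses Newton iterations with step-halving, so the
weighted log-likelihood is non-decreasing; with hard 0/1 memberships it
reproduces the unweighted multinomial fit exactly. Effects are reported
as relative risk ratios with Wald 95% CIs ($z = 1.96$) on the log scale.
Genotypes enter as additively coded 0/1/2 covariates like any other
numeric column. Apparent complete separation (|log RRR| > 15) and
non-convergence are flagged, not silently ignored.

`dlMeta()` pools per-cohort log effects by DerSimonian–Laird:
$Q = \sum w_i (y_i - \hat y_{FE})^2$ with $w_i = 1/se_i^2$,
$\tau^2 = \max\{0, (Q - (m-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$, and
inverse-variance pooling with weights $1/(se_i^2+\tau^2)$. A single study
is returned unchanged with $\tau^2 = 0$.

## The synthetic cohort generator

Cohort data of the kind this pipeline targets are not publicly
deposited, so `simulateCohort()` provides the test bed: a five-phenotype
Bernoulli mixture (never / early-transient / late-onset / persistent /
intermittent) with prevalences 54.1/23.7/6.9/8.3/6.9% (renormalised to
sum to 1) and class-conditional per-epoch wheeze probabilities shaped so
that ETW wheezes early and remits, LOW starts in middle childhood, PEW
wheezes throughout, and INT alternates. The class draw precedes the
indicator draws, which precede missingness, all from one seeded
generator, so a seed fully determines a cohort.

The default per-epoch probabilities are calibrated so that the latent
classes are *recoverable*: complete-case PAM on spell features attains
ARI > 0.9 against the truth and the cost-knee selects k = 5 at
n = 2,000. Softer settings (e.g. class noise of 2–3% per epoch) blur the
class boundaries enough that no method can reach that agreement — about
10% of never-wheezers then emit a wheezy epoch and become genuinely
indistinguishable from transient wheezers — so the defaults use noise
rates of 0.5–4% per epoch. This is a choice about what the generator
*is* (a recoverable ground truth for validating machinery), not a claim
about real cohorts.

Missingness mechanisms: per-cell MCAR; a simple informative MAR variant
in which the missingness probability doubles after a wheezy epoch (and
epoch 1, having no predecessor, is never missing); and subject-level
amputation (`amputeSubjects()`) in which a chosen proportion of subjects
loses 1–2 random epochs — the design used by the missing-data
experiment. What the generator does *not* emulate: covariates
(maternal asthma, smoking, birth weight), genotypes, cohort-specific
follow-up schedules, reporting error correlated within families, or
informative dropout. Passing tests therefore validate the machinery and
its contracts, not the clinical claims on any real cohort.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the recovery experiment
at n = 2,000, the missing-data consensus experiment at n = 3,000 with
M = 10 imputations, LCA checks at n = 10,000–20,000 (pattern-collapsed EM
makes these cheap), and brute-force oracle comparisons at n = 10 —
sizes at which every exhaustive oracle is computable exactly and the full
suite completes in minutes on one core. Other fixed numerics: distance
symmetry is enforced to 1e-12; EM tolerance 1e-8 (relative); Newton
tolerance 1e-10 with up to 20 step-halvings; all tie-breaks (medoid
choice, nearest-medoid assignment, argmax labels, modal k, permutation
search) resolve to the lowest index so that every stage is reproducible
bit-for-bit given a seed.

## Known limitations

* The cited mixed-data distance is implemented in its standard
  normalised Gower form (variance-standardised squared differences plus
  categorical mismatch with pairwise deletion); the original analysis
  does not print a formula, and whether it standardised by SD or range,
  or treated spell type as nominal or ordinal, is not stated — all four
  are exposed as options.
* Silhouette-based cluster-number selection degenerates on duplicated
  discrete data (see above); the cost-knee default is the package's own
  remedy and both statistics are reported.
* LCA parameter recovery is limited by near-saturation at T = 5, k = 5
  (see above) — a property of the design, not of the optimiser.
* The imputation model uses only the other epochs as predictors;
  auxiliary covariates are out of scope.
* `changedFraction()` aligns partitions by optimal relabelling before
  counting switches, since cluster numbers are arbitrary across
  independent fits; it requires equal cluster counts.
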