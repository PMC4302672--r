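---
title: "Molecular subtyping of bladder tumors with a self-organizing map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular subtyping of bladder tumors with a self-organizing map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(somtype)
```

## The problem

Bladder cancer develops along two broad molecular pathways — an indolent,
FGFR3-mutant, low-grade route and an aggressive, TP53-driven,
chromosomally unstable route — but individual tumors routinely carry
markers of both. Predicting which non-muscle-invasive tumors will
progress to invasion is the central clinical question, and no single
marker answers it. This package implements an unsupervised integration
strategy: summarize a panel of ten binary/ordinal genetic markers with a
small Kohonen self-organizing map (SOM), cluster the map's prototype
vectors ("virtual patients") into a two-level partition, assign real
patients to subclusters through their best-matching units, and then ask
(i) which markers are enriched where, and (ii) whether the partition
stratifies progression-free survival better than direct hierarchical
clustering of the patients.

The two-stage design — cluster the *prototypes*, not the patients — is
the method's defining feature. The SOM performs a topology-preserving
vector quantization of the cohort; Ward clustering then operates on a
small, denoised set of archetypal profiles instead of on noisy
individual patients.

## The map and its training

The map is a rectangular `rows x cols` lattice (default 4x4, sixteen
units) of prototype vectors $m_u \in [0,1]^{10}$. Training is the
*batch* Kohonen rule: in each epoch every patient $x_i$ is assigned to
its best-matching unit (BMU) $c_i = \arg\min_u \lVert x_i - m_u \rVert$,
and every prototype is replaced by the neighborhood-weighted mean

$$m_u \leftarrow \frac{\sum_i h(u, c_i)\, x_i}{\sum_i h(u, c_i)},
\qquad h(u, c) = \exp\!\left(-\frac{d_\mathrm{lattice}(u, c)^2}{2\sigma^2}\right),$$

with $d_\mathrm{lattice}$ the Euclidean distance between unit
coordinates on the lattice. One "presentation" of the dataset is one
epoch. Batch training is used (with the online rule available via
`mode = "online"` for comparison) because it is deterministic given the
initialization and matches the presentation-counting convention of
classical SOM toolboxes.

Training runs in two phases totalling 34 epochs:

| phase | epochs | $\sigma$ start | $\sigma$ end | purpose |
|-------|--------|-----------|---------|---------|
| rough | 7      | 2         | 1       | order the map globally |
| fine  | 27     | 1         | 0.25    | tune prototypes locally |

The epoch counts are the method's fixed configuration; the neighborhood
radii are this package's choice (the method's original description is
silent on them). They are set so the rough phase couples units across
half the 4x4 lattice and the fine phase ends close to a per-unit
centroid update ($\sigma = 0.25$ leaves nearest-neighbor coupling
$h = e^{-8} \approx 3\cdot10^{-4}$), which the test suite exploits: in
the $\sigma \to 0$ limit a batch epoch must equal a k-means centroid
step, and with one unit it must equal the data mean exactly.

**Initialization.** The default is *linear*: prototypes span the plane
of the two leading principal directions, laid out on a regular grid
$\bar{x} \pm \sqrt{\lambda_i}\, e_i$. It is deterministic (eigenvector
signs are fixed by making the largest-magnitude loading positive), so
the training seed only matters for `method = "random"` and for
downstream Monte Carlo. Degenerate all-constant data fall back to random
initialization with a warning.

**Encoding.** Binary markers enter as 0/1; $k$-level ordinal genotypes
as equally spaced scalars $\{0, \tfrac{1}{k-1}, \dots, 1\}$, keeping one
input neuron per variable and all features on the same $[0,1]$ scale, so
no further normalization is applied before training.

**The default ten features** are the nine binary tumor/viral markers
(CHEK2/FGFR3/TP53 mutation, altered TP53 expression, LOH at chromosomes
9/13/17, UroVysion positivity, HPV DNA) plus the binary CDKN2A A148T
genotype — the variables whose subcluster enrichment the analysis
targets. The three-level CYP1B1 and TP53 codon-72 polymorphisms are
loadable and encodable and can be added through `features =`, but are
kept out of the default map input: they are germline population
polymorphisms with weak subtype specificity, and including them would
force two of the tumor-level markers out of a ten-input configuration.
They remain in the subcluster report regardless.

## Partitioning the map

Prototypes are agglomerated with Ward's minimum-variance criterion
(`hclust` on squared Euclidean distances with `ward.D`; the
`ward.D2` variant is available via `squared = FALSE`; which variant the
original analysis used is not recoverable, and on these small prototype
sets the cut memberships rarely differ). The tree is cut at
$k = 2$ (main clusters X and Y) and $k = 4$ (subclusters); `cutree`
guarantees the cuts nest. Because cluster labels from a dendrogram are
arbitrary, they are canonicalized so tests and reports are stable:

- **X** is the main cluster whose units have the higher mean prototype
  value on the UroVysion feature (the aggressive, chromosomally unstable
  branch);
- subclusters are numbered within each cluster by decreasing unit
  count, ties broken toward the lowest unit index.

The $k=4$ cut is not forced to split 2+2 across X and Y; on some
cohorts it yields, e.g., X1, X2, X3, Y1, and all downstream code
handles any such split. Patients inherit the subcluster of their BMU;
units to which no patient maps are kept in the unit tables with
$n = 0$ — unoccupied neurons are a normal outcome when 104 patients
spread over 16 units.

## Subcluster statistics

Binary and categorical variables are tested with a **Monte Carlo
randomization test**: the omnibus statistic is the Pearson chi-square of
the subcluster-by-level contingency table, and its null distribution is
generated by permuting subcluster labels (default 9999 permutations).
The p-value uses the add-one estimator
$p = (1 + \#\{\chi^2_\mathrm{perm} \ge \chi^2_\mathrm{obs}\}) / (1 + B)$,
which is never zero — the smallest reportable value at $B = 9999$ is
$10^{-4}$. The chi-square is used purely as a permutation statistic, so
small expected counts are not a concern. Alongside the omnibus test,
each subcluster gets a **phi fidelity coefficient**

$$\phi = \frac{n\,n_p - n_t N_p}{\sqrt{n_t N_p (n - n_t)(n - N_p)}}$$

(the Pearson correlation of the membership and presence indicators),
with a one-sided permutation p-value supporting "significantly highest
in subcluster S" annotations on component planes. Group-size
equalization of phi is available (`equalize = TRUE`) but off by
default, as the subclusters of interest are near-equal in size.

Graded variables (grade, stage, tumor multiplicity, diameter class) are
tested with the tie-corrected **Kruskal–Wallis** test and the **Dunn
post hoc** test on mean ranks with tie-corrected pooled variance,
Bonferroni-adjusted by default (the adjustment is configurable; no
particular choice is canonical here). Report percentages are always
recomputed from counts, never transcribed, so the output table is
internally consistent by construction. Significance is additionally
printed in the conventional tiers (<0.05, <0.01, <0.001, ns). CYP1B1 is
collapsed to T/T homozygotes versus G-allele carriers inside the report
(`collapse_cyp1b1 = TRUE`), matching how such panels are conventionally
reported; the three-level form is available by flag.

## Survival analysis

Kaplan–Meier curves, k-group log-rank tests and Cox
proportional-hazards fits wrap the `survival` package behind a stable
interface (`km_estimate`, `logrank_test`, `cox_fit`,
`univariable_screen`). Ties are handled with the Breslow approximation
by default (Efron by flag). Non-convergence and monotone-likelihood
separation are flagged on the returned fit rather than raised, because
screens over many small subgroups routinely produce both. Progression
and recurrence are independent endpoints with separate time/event
columns. The test suite pins these wrappers to hand-computed
product-limit and hypergeometric O−E oracles and to the identity that
the two-group log-rank statistic equals the Cox score test at
$\beta = 0$.

The comparison arm (`hcluster_patients`) clusters patients directly
with city-block distance and average linkage, cut at $k = 4$ by default
to match the subcluster count; `compare_stratification` reports the
progression log-rank for both partitions side by side. No test asserts
that the map partition *beats* the baseline — that was an empirical
observation on one cohort, not a theorem; tests only require each
method to recover structure it is geometrically able to recover.

## The synthetic cohort generator

Patient-level data for the motivating study were never deposited, so
the package ships a seeded generator (`simulate_cohort`) whose defaults
reproduce the *published summary structure*:

- four archetypes named X1, X2, Y1, Y2 with mixing proportions
  24/104, 28/104, 24/104, 28/104;
- per-archetype marker probabilities equal to the published subcluster
  frequencies (e.g. FGFR3 mutation 1.0 in Y2, UroVysion 0.0 in Y1);
- clinical covariates (grade, stage, diameter, multiplicity, smoking,
  occupational exposure, age, sex) from the per-subcluster
  distributions, with the published G2–3 share split 70/30 between G2
  and G3;
- exponential progression times with hazard
  $\lambda_0 \exp(\ln 2.9 \cdot (\mathrm{grade}-1) + \ln 3.8 \cdot \mathrm{HPV})$
  — grade and HPV are the planted independent predictors — and
  uniform censoring on [6, 60] months. The baselines
  ($\lambda_0 = 0.001562$/month for progression, 0.008161/month for
  recurrence) come from a one-time calibration so that a default
  cohort shows roughly 14% progression and 23% recurrence.

`generate_null_cohort` draws every variable independently from the
pooled marginals with covariate-free hazards, for type-I-error and
calibration checks.

**The key simplification:** markers are conditionally independent given
the archetype. Only per-subcluster marginals are published; real tumors
certainly carry within-subtype marker correlations (e.g. between the
three LOH variables). Consequently, passing tests demonstrate that the
pipeline recovers *mixture-of-independent-Bernoulli* structure and
calibrated survival effects; they do not demonstrate performance under
correlated noise, batch effects, or missing data, none of which the
generator emulates.

**What recovery is possible:** two of the default archetypes (X1 and
X2) differ only in a handful of moderately penetrant markers, so the
classes overlap substantially — even an oracle Bayes classifier built
from the true generative parameters misassigns an appreciable fraction
of patients. Full recovery of the default archetypes is therefore
impossible by construction, and the end-to-end recovery check in the
acceptance suite documents this honestly rather than passing. On
well-separated archetypes (pairwise Hamming distance ≥ 6 of 10
features, flip noise ≤ 5%) the pipeline recovers the planted partition
essentially perfectly, which is the regime the map's geometry can
resolve.

## Numerical choices

- BMU ties break toward the lowest unit index; all argmins are
  deterministic.
- Batch-update denominators below $10^{-12}$ (a unit receiving no
  neighborhood mass) leave that prototype unchanged.
- Eigenvector signs in the linear initialization are fixed by making
  the largest-magnitude loading positive.
- Permutation counts: default 9999 (floor 999, enforced); the add-one
  estimator keeps p in $[1/(B+1), 1]$.
- Chi-square comparisons in the permutation loop use a $10^{-12}$
  tolerance so ties at the observed statistic count as "as extreme",
  keeping the test conservative.
- Merge heights from Ward linkage are checked for monotonicity; a
  violation is reported as a defect rather than silently reordered.
- Cohort validation is strict: missing values are a load-time error by
  default (`on_missing = "drop"` opts into row deletion); imputation is
  deliberately out of scope.

## Problem sizes used in the checks

The shipped test-suite simulations use cohorts of 104–2000 patients
(100 000 for marginal-frequency checks), 50 pipeline runs at $n = 300$
for end-to-end recovery, 2000 null datasets of $n = 40$ for test-size
calibration, and 999–9999 permutations per randomization test — sizes
chosen so the full suite completes in a few minutes on a single CPU
while keeping Monte Carlo standard errors well inside the asserted
margins.

## Known limitations

- The SOM and the Ward cut are fit to one cohort at a time; no
  out-of-sample assignment API beyond `find_bmu` on a frozen map.
- No missing-data handling beyond strict rejection.
- No correction for multiple testing across the variable panel (per
  convention for this report style); interpret per-variable p-values
  accordingly.
- Hexagonal/toroidal lattices, growing maps, consensus clustering and
  automatic selection of the number of clusters are out of scope.
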