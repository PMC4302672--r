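# somtype

Unsupervised molecular subtyping of bladder-tumor cohorts with a
Kohonen self-organizing map (SOM).

Bladder cancer progresses along two broad molecular routes — an
indolent FGFR3-mutant pathway and an aggressive TP53/chromosomal
instability pathway — yet single markers predict progression poorly.
`somtype` implements an integration strategy for panels of pre-called
genetic markers (mutations, LOH calls, FISH positivity, genotypes): a
small SOM quantizes the cohort into prototype "virtual patients",
hierarchical clustering of those prototypes defines a two-level
partition, and patients inherit subtypes through their best-matching
units. The package then characterizes the subtypes statistically and
tests whether they stratify progression-free survival.

## The method

A 4×4 lattice of prototypes $m_u \in [0,1]^{10}$ is trained by the
batch Kohonen rule over 34 whole-cohort presentations (7 rough epochs
with neighborhood radius σ: 2→1, then 27 fine epochs, σ: 1→0.25):

$$m_u \leftarrow \frac{\sum_i h(u,c_i)\,x_i}{\sum_i h(u,c_i)},\qquad
h(u,c)=e^{-d_{\mathrm{lattice}}(u,c)^2/2\sigma^2},$$

where $c_i$ is patient $i$'s best-matching unit. Prototypes are then
agglomerated with Ward linkage (squared Euclidean) and the tree cut at
k = 2 (clusters X/Y, X being the UroVysion-high branch) and k = 4
(subclusters). Subcluster enrichment of each binary marker is tested by
Monte Carlo randomization (chi-square omnibus over the subcluster ×
presence table, labels permuted, add-one p estimator) together with the
phi fidelity coefficient per subcluster; graded variables use
Kruskal–Wallis with Dunn post hoc. Survival machinery (Kaplan–Meier,
k-group log-rank, Breslow-tie Cox regression) wraps the `survival`
package. A direct patient-level clustering arm (city-block distance,
average linkage) provides the head-to-head comparison.

Because the motivating study deposited no patient-level data, the
package includes a seeded cohort generator whose defaults plant four
molecular archetypes with the published subcluster marker frequencies
(mixing 24/104, 28/104, 24/104, 28/104) and exponential progression
hazards driven by grade (HR 2.9 per step) and HPV DNA (HR 3.8), with
~14% progression / ~23% recurrence under uniform [6, 60]-month
censoring. See `vignette("som-subtyping")` for the full methodology and
its limitations.

## Worked example

```r
library(somtype)

coh <- simulate_cohort(n = 104, seed = 11)   # synthetic 104-patient cohort
st  <- subtype_cohort(coh, seed = 11)        # encode -> train -> cluster -> assign
st$fit
#> som_fit: 4x4 map, 10 features, 34 epochs
#>   final quantization error 0.5303, topographic error 0.3269

table(st$partition$patient_subcluster)
#> X1 X2 X3 Y1
#> 36 31 16 21
```

On this cohort the k = 4 cut splits the UroVysion-positive cluster X
into three subclusters and leaves Y whole — the cut follows the
dendrogram, not a forced 2+2 layout. The subcluster report shows which
markers define the groups:

```r
rep <- subcluster_report(coh, st$partition, n_permutations = 9999, seed = 12)
rep$table[rep$table$variable %in% c("fgfr3_mut", "urovysion_pos"), ]
#>       variable level         X1         X2         X3        Y1 p_value p_label
#>      fgfr3_mut     1 36 (100.0)    0 (0.0)    0 (0.0) 10 (47.6)   1e-04  <0.001
#>      fgfr3_mut     0    0 (0.0) 31 (100.0) 16 (100.0) 11 (52.4)      NA      ns
#>  urovysion_pos     1 36 (100.0)  30 (96.8)  15 (93.8)   1 (4.8)   1e-04  <0.001
#>  urovysion_pos     0    0 (0.0)    1 (3.2)    1 (6.2) 20 (95.2)      NA      ns
```

Every FGFR3-mutant patient landed in X1 or Y1 and UroVysion positivity
cleanly separates Y1 from the X branch; both enrichments reach the
smallest reportable permutation p (1/10 000). Finally, the survival
comparison against direct patient clustering:

```r
base <- hcluster_patients(st$X, k = 4)
compare_stratification(coh, st$partition, base)
#>  partition n_groups statistic df   p_value
#>        som        4  1.883846  3 0.5968612
#>   baseline        4  5.456593  3 0.1412580
```

With only ~15 progression events in 104 patients neither partition
stratifies progression significantly here — survival power at this
cohort size is limited, which is itself an honest property of the
design (the test suite verifies the planted hazards are recovered at
n = 2000).

`run_pipeline(pipeline_config(...), out_dir)` executes the whole chain
and writes the artifact set (cohort summary, unit/patient tables,
component planes, subcluster report, univariable screen, KM curves,
stratification comparison) plus a `manifest.json` with all seeds.

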