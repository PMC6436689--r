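---
title: "Prototype-based screening for SNP-SNP compositional epistasis: models and methods"
author: "episcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-based screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The problem

Genome-wide searches for SNP-SNP interactions usually score every pair of
SNPs by first choosing a *disease model* — a rule that maps the 3 × 3 table
of genotype combinations to a binary high/low-risk assignment — and then
testing whether that assignment is associated with case-control status.
The space of such rules is the set of two-locus, two-allele, two-phenotype,
complete-penetrance (TTTC) models: 2^9 − 2 = 510 non-trivial binary 3 × 3
tables.  The popular baselines pick the rule from the data itself: MDR
labels a cell high-risk when its case:control count ratio clears a
threshold, and the ratio-split (RS) rule sorts the nine cells by that ratio
and tests the eight nested top-*x* partitions.  Both use the data twice —
once to choose the model, once to test it — which inflates the nominal
statistics and, especially at small sample sizes, produces spurious hits.

The method implemented here fixes the candidate models *a priori*.  All 510
models are reduced by the locus-exchange (transpose) and disease-status
exchange (complement) symmetries to 143 representatives, clustered under a
population-calibrated distance, and `K = 7` prototypes are retained per
pair of minor-allele-frequency (MAF) bins.  Screening then tests each SNP
pair only against the prototypes for its MAF bins (plus their transposes),
so the per-pair model search is limited and identical for every pair.

## The model distance

The similarity of a prototype `M'` to a true model `M` is the
phi coefficient of the 2 × 2 cross-classification of a hypothetical
case-control sample into high/low risk by the two models:

$$
\Phi(M', M) \;=\;
\frac{W_{11}W_{00} - W_{10}W_{01}}
{\sqrt{\Bigl(\tfrac{U}{V}W_{11} + W_{01}\Bigr)
       \Bigl(W_{10} + \tfrac{V}{U}W_{00}\Bigr) W_{1\cdot} W_{0\cdot}}},
\qquad d(M', M) = 1 - \Phi(M', M),
$$

where \(W_{k\ell}\) sums the Hardy–Weinberg genotype-combination
probabilities over cells with \(M = k\) and \(M' = \ell\),
\(U = rP_1(1-P(D)) + (1-P_1)P(D)\) and \(V\) likewise with \(P_0\),
\(r\) is the sample case:control ratio, and the two penetrance levels
\(P_1 > P_0\) of the true model follow in closed form from the prevalence
\(P(D)\) and heritability \(h^2\):

$$
P_1 = P(D) + \sqrt{\tfrac{W_{0\cdot}}{W_{1\cdot}}P(D)(1-P(D))h^2},
\qquad
P_0 = P(D) - \sqrt{\tfrac{W_{1\cdot}}{W_{0\cdot}}P(D)(1-P(D))h^2}.
$$

The distance is directional: `M` is the reference whose penetrance levels
are calibrated, and `M'` the stand-in.  Two structural anchors pin the
denominator down, and both are enforced by tests: when `r` equals the
population ratio \(P(D)/(1-P(D))\) the expression collapses to the plain
concordance phi, and the two bracketed factors expand to the
case-control-weighted variance decomposition of `M'`.  The implementation
is additionally validated against a Monte-Carlo oracle that simulates a
large retrospective sample and computes the empirical phi directly.

Defaults follow the package-wide population assumption
`prevalence = heritability = 0.02` and `sampleRatio = 1` (balanced
case-control), with Hardy-Weinberg equilibrium throughout; linkage
disequilibrium between SNPs is out of scope.

### Feasibility and orientation

The closed form above requires \(P_0 \ge 0\) and \(P_1 \le 1\).  At the
default prevalence and heritability this bounds the risky genotype mass:
a model whose risky cells carry more than
\(P(D)/\bigl((1-P(D))h^2 + P(D)\bigr) \approx 0.505\) of the probability
has no valid two-level penetrance, and at extreme MAFs a model whose risky
mass is nearly zero fails on the other side.  A model and its complement
describe the same risky/non-risky *partition*, and the screening statistic
is invariant under complementing the risk vector, so the library build
represents every partition in its feasible (small-risky-mass) orientation
at each bin pair.  Only partitions infeasible in both orientations — e.g.
the double-recessive corner cell at MAF 0.05, whose risky mass is of order
\(10^{-5}\) — are dropped from that bin's clustering.

## Prototype selection

For each ordered pair of MAF bins on the grid
{0.05, 0.1, 0.2, 0.3, 0.4, 0.45} (36 entries), the build computes the full
directional distance table over the oriented representatives and runs the
incremental *global K-means* algorithm: starting from an empty prototype
set, each step evaluates every remaining model as a potential new center by
assigning all models to their nearest center and summing within-cluster
distances, then appends the minimizer.  The first prototype is therefore
the exact medoid, the objective is non-increasing, and the whole procedure
is deterministic (ties break to the lexicographically smallest id).

Two genuinely open design points were settled empirically, and the choices
are part of the package's definition:

* **Orientation of the clustering distance.**  The directional metric can
  enter the within-cluster sum with the center as the stand-in or with the
  center as the reference.  With the center as stand-in, the selection
  collapses onto a nested family of high-risk-mass models — near-copies of
  one another whose induced partitions fit none of the classical epistatic
  mechanisms well.  With the center as the *reference* model and the
  members as stand-ins (the implemented choice), the selected sets are
  structurally diverse and the downstream screening behaviour reproduces
  both the null-inflation profile and the detection-power pattern that the
  replication studies in `tests/` and `scripts/acceptance.R` check.
* **Continuity correction.**  The nominal association measure is the 1-df
  chi-square of the induced 2 × 2 risk-by-status table *with* the classical
  continuity correction; `chi2Test(..., correct = FALSE)` gives the plain
  Pearson form.  The corrected statistic is what the null-inflation
  replication reproduces; the uncorrected one is systematically larger on
  sparse tables.

At screening time a pair's two control-sample MAFs are mapped to the
nearest grid values (exact midpoints round down), the matching entry is
fetched, and every prototype *and its transpose* (when locus-asymmetric)
is tested, so the symmetry reduction never hides an orientation.

## Screening procedures

`marginalScreen()` scores each unordered pair independently and ranks by
the nominal statistic.  `sequentialScreen()` selects pairs one at a time:
after each selection the accumulated high-risk assignment (elementwise OR
of the selected models' risk vectors) is fixed, and every remaining pair is
re-scored by the chi-square of the OR of that history with the candidate's
own assignment.  Each method re-chooses the candidate's model per round to
maximize this conditional statistic (`refitModels = FALSE` reuses the
marginal choice; MDR's ratio-determined model never changes).  Missing
genotypes are handled complete-case per pair.  Ties break deterministically
by statistic, then SNP indices.

`selectModelMdr()` generalizes the balanced "ratio ≥ 1" rule to the
sample's case:control ratio; cells with cases but no controls are
high-risk, truly empty cells low-risk.  `selectModelRs()` ranks empty
cells last and breaks ranking ties by row-major cell index, then prefers
the smaller split on equal statistics.

## The simulation harness

All study conditions are generated by retrospective sampling: the
distribution of the causal genotypes *conditional on status* is computed
exactly by Bayes' rule over the 9 (one causal pair) or 81 (two pairs)
genotype states with HWE priors, and causal genotypes are drawn from it;
noise SNPs are independent HWE draws.  This is exact and fast at low
prevalence, and the sampler is validated against the analytic conditional
law in the tests.  Scenario presets fix the published study conditions:

* `ex2.1-1` / `ex2.1-2` — two SNP pairs with binary risk partitions and
  four penetrance levels \(p_{k\ell}\), with \(p_{11}\) solved from the
  equal-case-control-ratio (pathological) condition
  \(p_{11} = p_{01} - (\sum_{N} v / \sum_{R} v)(p_{10} - p_{00})\);
  100 SNPs, n = 800, all MAFs 0.3 (or 0.2).
* `ex2.2` — two additive-penetrance pairs acting independently, combined
  by the union rule \(1 - (1-f_1)(1-f_2)\); causal MAFs 0.5 and 0.3 within
  each pair, noise MAFs uniform on [0.05, 0.5], n = 200.
* `null-0.05` / `null-0.10` / `null-0.40` — 100 unrelated HWE SNPs,
  phenotype independent, n = 400 balanced.
* `T` / `DD` / `MOD` / `XOR` / `ME` / `MET` at MAF 0.1 (n = 600) or 0.4
  (n = 300) — odds-parameterized families, cell odds
  \(\alpha(1+\theta)^e\) with family-specific exponents; \(\alpha\) and
  \(\theta\) are solved by nested root-finding so the implied penetrance
  table reproduces prevalence 0.02 and the family's heritability (0.02, or
  0.015 for the multiplicative families) to 10^-8.
* `DMN1`–`DMN4` — fixed multi-level penetrance tables with (near) no
  marginal effects, MAF 0.25 or 0.1, n = 600.

All "total n" sample sizes are split into equal cases and controls.  The
generator emulates independent biallelic SNPs under HWE with a binary
phenotype; it does not model linkage disequilibrium, population structure,
genotyping error or missingness mechanisms, so passing the replication
studies says nothing about robustness to those features of real data.

## Evaluation drivers

`fMeasure()` implements the single-true-pair information-retrieval score
(precision `1/#detected` when the truth is detected, recall the detection
indicator).  `bonferroniThreshold()` gives the two published corrections
(pairs only, and pairs × the 8 RS candidates).  `replicateExperiment()`
runs simulate–screen–score loops with per-replication seeds
`baseSeed + r`, sharing each simulated dataset across methods, and
aggregates the mean and standard error (sample SD / √reps) of the
appropriate metric — F-measure (marginal), top-2 detection counts
(sequential) or mean nominal chi-square (null).

The replication studies in the test suite and the acceptance script use
100 replications per setting (the original studies used 400) and compare
against the published values with tolerances widened by √(400/reps); the
problem sizes (100 SNPs, 4,950 pairs per replication) match the original
study throughout.

## Known limitations

* The per-bin prototype sets depend on every detail of the clustering:
  metric calibration, feasibility handling, orientation and tie-breaks.
  The published description leaves several of these open, and the original
  per-bin sets themselves are not published; where our reconstruction's
  sets differ, detection-power results that are sensitive to single
  prototypes (notably scenarios whose causal SNPs carry strong marginal
  effects) can deviate substantially even though the null-inflation
  behaviour, the metric identities and the clustering diagnostics all
  reproduce.  The acceptance checks report these quantities regardless.
* The directional metric presumes the true pair is the one under test and
  that the true model is two-level; multi-level tables (the multiplicative
  families, the DMN tables) are screened through their best two-level
  approximation among the prototypes.
* Sequential screening re-fits candidate models per round; the alternative
  (reusing marginal choices) is available but shifts selection frequencies
  slightly in the two-pair scenarios.
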