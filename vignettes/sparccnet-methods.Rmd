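---
title: "Methods: sample-specific SparCC networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific SparCC networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparccnet)
```

## The estimator

Sequencing yields relative abundances `x_i^(k)` (taxon i, sample k); the
quantity of ecological interest is the correlation of the latent
absolute ("basis") abundances. Ratios are unaffected by the
compositional closure, so SparCC starts from the per-pair log-ratio
variance

\[ t_{ij} = \mathrm{Var}\!\left[\log \frac{x_i}{x_j}\right]
 = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j , \]

with \(\omega_i^2\) the log-basis variance of taxon i. Assuming the
average pairwise correlation is negligible (sparsity), the system
linearizes and, writing \(a = 2D-3\) and \(b = 1/(2(D-1)(D-2))\) for a
table of \(D\) taxa,

\[ \omega_i^2 = b(a+1)\sum_j t_{ij} - b\sum_{i,j} t_{ij}, \qquad
   \rho_{ij} = \frac{\omega_i^2 + \omega_j^2 - t_{ij}}{2\omega_i\omega_j}. \]

`sparcc()` implements exactly this one-pass analytic solution. The
original SparCC's iterative exclusion of strongly correlated pairs is
deliberately **not** applied: the per-sample decomposition below is an
algebraic identity of the analytic form, and an iterative refit would
destroy it. The cost is a mild attenuation bias when many strong
correlations are present (visible in the planted-block recovery tests,
where within-block correlations of 0.8 are estimated around 0.6–0.75 —
still comfortably above the 0.4 clustering threshold).

Numerical choices:

* **Population variance** (divide by \(S\), not \(S-1\)). The
  per-sample decomposition carries an explicit \(1/S\); only the
  population form makes the per-sample contributions sum exactly to the
  cohort estimate.
* **Negative basis variances.** The closed form can go negative when
  sparsity is badly violated; estimates are floored at \(10^{-12}\)
  with a warning rather than silently producing `NaN`.
* **Clipping.** \(\rho\) is clipped to \([-1, 1]\) for reporting, but
  the unclipped matrix is retained: the decomposition identity and the
  inversion identity \(t_{ij} = \omega_i^2+\omega_j^2-2\rho_{ij}
  \omega_i\omega_j\) hold only for unclipped values.
* **Zeros.** Counts get a pseudocount (default 0.5, the customary
  choice) before row normalization; the prevalence filter counts
  strictly positive cells *before* the pseudocount.

## One network per sample

With centred log abundances \(z_i^{(k)}\) and squared deviations
\(d_{ij}^{(k)} = (z_i^{(k)} - z_j^{(k)})^2\) (note
\(t_{ij} = \tfrac1S\sum_k d_{ij}^{(k)}\)), each correlation splits into
per-sample summands

\[ \rho_{ij}^{(k)} = \frac{b(a+1)\bigl(R_i^{(k)} + R_j^{(k)}\bigr)
   - 2b\,T^{(k)} - d_{ij}^{(k)}}{2 S \omega_i \omega_j}, \qquad
   \sum_k \rho_{ij}^{(k)} = \rho_{ij}, \]

where \(R_i^{(k)} = \sum_j d_{ij}^{(k)}\) and
\(T^{(k)} = \sum_{ij} d_{ij}^{(k)}\). `sparcc_decompose()` computes the
full \(S \times D \times D\) tensor; the identity is verified to
\(10^{-8}\) in the test suite across 50 seeded tables. The cohort means
and variances are estimated on **all** S samples, including sample k —
a reference-set convention with no leave-one-out. A useful consequence
of the centring: a sample lying exactly on the cohort geometric-mean
profile has \(d_{ij}^{(k)} = 0\) for every pair and contributes exactly
zero — the SSN measures deviation from the cohort reference.

**Edge rule.** Which \(\rho_{ij}^{(k)}\) constitute an "edge" of a
personal network is a genuinely open design choice, so it is an
explicit, logged parameter rather than a hidden constant. The default
retains pairs with \(|\rho^{(k)}| \ge \tau\), with \(\tau\) chosen by
`ssn_threshold()` so that the *median* network density across the
cohort hits a target (default 10% of the \(D(D-1)/2\) candidate
pairs). A single shared \(\tau\) keeps edge counts comparable between
individuals — the property the responder analysis relies on — while
remaining reportable. A per-sample top-q rule is available
(`top_q`), with deterministic lexicographic tie-breaking. Signed
edges are retained throughout.

## Co-abundance groups

`bootstrap_sparcc()` defaults to **permutation** pseudo p-values: each
of 100 replicates shuffles every taxon column independently, and a
pair's p-value is the add-one-smoothed fraction of replicates whose
\(|\rho^*|\) reaches the observed magnitude. A bootstrap of the
estimator does not by itself test any null; since the downstream rule
is "correlation > 0.4 **and** p < 0.05", a proper null distribution is
required, and resampling-with-replacement is kept behind
`method = "bootstrap"` (sign-stability p-values) for users who want the
original flavour.

`cluster_cags()` keeps edges with \(\rho > 0.4\) (positive only by
default — co-*abundance* groups rise and fall together; `use_absolute`
flips this) and p < 0.05, takes connected components, and refines
components of three or more taxa by average-linkage clustering on
\(1-\rho\) cut at height \(1 - r_{thresh}\), so chains glued by single
edges do not produce sprawling groups. Unlinked taxa become singleton
CAGs, which keeps `cag_abundance()` exactly total-preserving per
sample. No named clustering algorithm is canonical for CAGs; the
component-plus-average-linkage choice respects the hard edge threshold
while producing compact groups, and the linkage record is stored in the
output.

## Group-level networks, hubs, robustness

`cooccurrence_network()` links features whose Spearman correlation has
p < 0.05 (no multiplicity adjustment — the convention for these
descriptive networks), signed by the sign of rho; constant columns
yield no edges. P-values use `stats::cor.test()`, which switches
between the exact small-sample distribution and the t-approximation.

Hubs ("keystone taxa") are nodes holding more than 4% of all degree
ends. Degree sequences are reported sorted for distribution
inspection; no formal power-law fit is made.

Robustness removes all N nodes in a uniformly random order, recording
after each removal the largest-connected-component fraction
\(\sigma\) (0 for the empty graph). The removal order is the natural
one — the printed description of sorting fragility values in
"decreasing order" is read as describing the monotone shape of the
curve, since sorting is a no-op on the already non-increasing per-order
curves and the natural order reproduces the analytic complete-graph
value. With the across-replicate median (default 1000 orders) as the
final curve,

\[ R = \frac1N \sum_{i=1}^{N} \sigma(i/N), \]

which is exactly \((N-1)/2N\) for complete graphs (0.45 at N = 10,
asserted in the tests) and 0 for a single node. Median aggregation
means R can differ slightly from the exhaustive-mean value on
asymmetric graphs (the tests bound the difference on small graphs
enumerated exhaustively). The union-find implementation adds nodes in
reverse order, so a replicate costs O(N + E) rather than N component
searches.

## Responder prediction

Responder ⇔ HFC change < −5 (strict; −5.0 exactly is a
low/non-responder, "decreased by more than 5%"). Three predictors are
provided:

1. **Unsupervised:** `roc_attribute()` sweeps one SSN attribute (edge
   count or mean degree). AUC is the Mann–Whitney statistic with
   midranks, oriented so that higher attribute scores toward responder;
   an AUC below 0.5 plus the reported direction flags the opposite
   orientation rather than silently flipping.
2. **Supervised:** `fit_penalized()` regresses *post-intervention HFC
   level* (not the change) on the \(D(D-1)/2\) edge features, by
   Elastic-Net (mixing 0.5, the default) or LASSO — both are exposed
   because both appear in practice. The penalty is chosen by
   cross-validation, leave-one-out by default since intervention arms
   have 10–20 participants; predictions minus baseline give predicted
   changes, thresholded at −5 into predicted labels, and ROC is
   reported for resubstitution and held-out predictions separately
   (they differ substantially at this n, so neither is hidden).
3. **Regression:** `regress_attribute()` is plain OLS of HFC change on
   a single pre-specified attribute with the usual two-sided slope
   test; no multiple-testing adjustment because there is one
   predictor.

## The synthetic cohort generator

`simulate_counts()` draws log-normal basis abundances (default
log-means N(0, 1.5²), log-SDs uniform on [0.5, 1.5] — uneven taxa with
moderate dispersion, as in real gut profiles), with planted pairwise
or block correlations (nearest-PSD repair for mildly indefinite
plants, an error beyond a 0.1 repair tolerance), normalizes, and draws
multinomial reads at fixed depth — emulating tables rarefied to a
common depth (default 10,000 reads, the usual rarefaction level).
Estimable truth is the latent log correlation, which is exactly what
SparCC targets; the latent draws are attached to the table so
generative tests can check against pre-compositional truth.

`simulate_cohort()` adds a per-sample standard-normal "connectivity"
score that (a) multiplies the sample's deviation from the cohort mean
log composition by `exp(0.6 × score)`, inflating that sample's
per-sample correlation magnitudes and hence its SSN density, and (b)
subtracts `effect` (default 4 percentage points per SD) from the HFC
change, plus N(0, noise²) noise (default 2). The mean change is
positioned so the expected responder fraction at the −5 cutoff equals
`responder_frac` (default 0.5); baseline HFC is uniform on 8–35%,
the range typical of NAFLD cohorts. Defaults correspond to a strong,
cleanly detectable coupling (correlation ≈ −0.9 between score and
change); with `effect = 0` the phenotype is independent of the
microbiome and the pipeline must return chance-level AUC, which is the
calibration check in the tests.

What the generator does **not** emulate: zero-inflation beyond
multinomial sampling, taxonomic structure, platform (16S vs shotgun)
differences, longitudinal dependence between baseline and follow-up
samples, or covariates (age, BMI). Passing tests therefore demonstrate
correctness of the estimators and the internal consistency of the
pipeline under the stated generative model, not clinical performance
on real cohorts.

## Problem sizes and runtimes

The validation suite uses the scales the methods are designed for:
decomposition identity on 50 tables of 20 taxa × 30 samples; recovery
at 50 taxa with 50–500 samples; CAG recovery with three planted blocks
of 8 taxa at 300 samples and 100 resampling replicates; robustness
with 1000 removal orders at N = 10–20; responder calibration over 50
seeded cohorts of n = 20 per condition. The complete suite runs in
well under a minute on a laptop; `scripts/acceptance.R` re-derives the
same quantities in a few seconds.

## Known limitations

* The one-pass estimator inherits SparCC's sparsity assumption; dense
  strong correlation structures bias all estimates downward (the floor
  on negative basis variances is the symptom's guard rail).
* SSN edge counts depend on the cohort used as reference; networks from
  different cohorts are not directly comparable.
* Permutation p-values are lower-bounded by 1/(n_boot + 1); with the
  default 100 replicates the smallest achievable p is ~0.0099, which is
  adequate for a 0.05 rule but not for stringent thresholds.
* At n ≈ 10–20, leave-one-out ROC estimates are noisy; resubstitution
  AUCs are optimistic. Both are reported, neither is corrected.
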