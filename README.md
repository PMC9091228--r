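# sparccnet

Sample-specific SparCC networks for compositional microbiome data.

## The problem

Relative-abundance tables from 16S or shotgun sequencing are
compositional: every row sums to one, so ordinary correlations between
taxa are spurious. SparCC works around this by using log-ratio variances

```
t_ij = Var[ log(x_i / x_j) ] = omega_i^2 + omega_j^2 - 2 rho_ij omega_i omega_j
```

where `omega_i^2` is the variance of the latent log *basis* (absolute)
abundance of taxon i and `rho_ij` the basis correlation one actually wants.
Under the sparsity assumption that the average pairwise correlation is
negligible, the basis variances have the closed form (with `a = 2D - 3`,
`b = 1 / (2 (D-1)(D-2))`, D taxa, S samples)

```
omega_i^2 = b (a + 1) * sum_j t_ij  -  b * sum_ij t_ij
```

and `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`.

A cohort-level correlation, however, says nothing about one patient.
Because `t_ij` is a sum of per-sample squared deviations, the estimate
decomposes exactly into per-sample summands `rho_ij^(k)` with
`sum_k rho_ij^(k) = rho_ij`. Each individual's summand slice is a
**single-sample network (SSN)**: a personalized co-occurrence network
built against the cohort reference. This package implements that
decomposition plus the analysis machinery around it:

* co-abundance groups (CAGs): SparCC with permutation/bootstrap
  significance (default 100 replicates), clustering at rho > 0.4 and
  p < 0.05 after a 20% prevalence filter;
* group-level Spearman co-occurrence networks (p < 0.05 edges), hub
  (keystone-taxon) detection at a 4% degree share, and robustness
  `R = (1/N) sum_i sigma(i/N)` under random node removal (median of
  1000 removal orders);
* responder prediction for lifestyle-intervention cohorts: a
  participant is a responder when hepatic fat content (HFC) drops by
  more than 5 percentage points; SSN edge counts feed an unsupervised
  ROC classifier, and the full edge matrix (D(D-1)/2 features) feeds
  Elastic-Net/LASSO models of post-intervention HFC;
* a synthetic-data generator (log-normal basis + multinomial reads at
  fixed depth, default 10,000) with planted correlations and a planted
  coupling between network density and HFC change, so every stage can
  be validated against known truth.

Intended users are microbiome researchers who want per-individual
network features from standard feature tables (TSV or BIOM).

## Worked example

```r
library(sparccnet)

mod <- basis_model(20, seed = 42)                       # 20-taxon basis model
sim <- simulate_cohort(mod, n = 20, effect = 4, seed = 43)
tab <- prevalence_filter(sim$table, 0.2)

fit <- sparcc(tab)
fit
#> sparcc_fit: 20 taxa, 20 samples
#>   off-diagonal rho: median -0.018, range [-0.713, 0.731]

tensor <- sparcc_decompose(tab)          # per-sample correlation slices
ssns <- build_ssn_all(tensor, density = 0.1)
ssns[[1]]
#> ssn 'S1': 20 taxa, 50 edges (mean degree 5.00)

labels <- label_responders(sim$meta, cutoff = -5)
table(labels$label)
#>         responder low/non-responder
#>                 6                14

edge_count <- vapply(ssns, `[[`, 0, "edge_count")
roc_attribute(edge_count, labels)
#> roc_result: AUC = 0.970 (higher_attribute_responder)

reg <- regress_attribute(edge_count, sim$meta$hfc_change)
#> slope = -0.076, r2 = 0.759, p = 5.859e-07
```

The AUC of 0.97 says baseline SSN edge counts separate responders from
low/non-responders almost perfectly in this simulated cohort (the
generator plants exactly that coupling); the negative regression slope
says each extra baseline edge predicts a larger drop in liver fat.

A command-line wrapper with subcommands `simulate`, `sparcc`, `ssn`,
`cags`, `network`, `robustness` and `predict` is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sparccnet.R", package = "sparccnet"))')" \
    simulate --taxa 50 --samples 20 --cohort --out runs/sim --seed 1
```

Every run writes a `manifest.json` with the effective configuration and
input checksums.

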