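# cascadeomics

Temporal multi-omic cascade network inference with prior-weighted stability
selection.

## What it is for

When a cell population is stimulated through a surface receptor, the
response unfolds in waves: immediate-early genes within the first hour,
secondary transcriptional targets over the following hours, and protein
effectors one to four days later. `cascadeomics` is for analysts with paired
transcriptomic and proteomic time courses of such a response — nine
measurement indices (T0 plus T1-T8, spanning 1-96 h), a handful of
individuals, a responsive group and a control group — who want to go from
raw count/intensity matrices to a directed, temporally ordered gene-protein
regulatory network and the proliferation-related subnetwork inside it.

## The model

Each actor (a transcript or a protein, by symbol) belongs to a temporal
cluster m(n), the rank of its first significant response time. Its scaled
profile is modeled as a sparse combination of same-or-earlier-wave actors:

    x̃_np· = Σ_n' ω_n'n F_m(n')m(n) x̃_n'p· + ε_np ,   p = 1..P

with F_ij a strictly lower-triangular-in-time T×T transfer matrix (earlier
source values drive strictly later target values) and ω the signed edge
weights whose sparsity defines the network. Estimation alternates a LASSO
over the stacked individuals (prior-knowledge edges get a reduced penalty
factor κ) with a ridge refit of the transfer matrices, the penalty is chosen
by leave-one-individual-out cross-validation, and edges are retained by
stability selection: B = 100 refits on random half-subsamples, keeping edges
selected in at least a fraction π = 0.6 of them.

The package also ships a synthetic-data generator that plants a scale-free
layered cascade with known edges, simulates negative-binomial transcript
counts and left-censored log-intensity proteins with a translation delay,
and serves as the ground truth for recovery benchmarking; moderated-t
differential signatures (temporal, response, and their intersection, the
proliferative signature); gene-protein concordance and translation-delay
estimation; and annotation-seeded subnetwork extraction with a three-layer
stratification.

## Worked example

```r
library(cascadeomics)

net <- generate_network(n_actors = 10, n_clusters = 2, mean_out_degree = 1.5,
                        knockout_fraction_of_cluster1 = 0, seed = 1)
net
#> <ground_truth_network> 10 actors, 2 clusters, 15 edges, 0 knockouts

cfg <- sim_config(noise_sd = 0, count_dispersion = 0,
                  protein_missing_rate = 0, seed = 1)
sim <- simulate_dataset(net, cfg, "proliferative")
x <- sim$latent[, -1, ]                       # post-stimulation series
clusters <- assign_clusters_from_series(x)

grid <- lambda_grid_default(x, clusters)
lam <- cross_validate_lambda(x, clusters, NULL, grid)$lambda_best
fit <- fit_cascade(x, clusters, lambda = lam, max_iter = 1, refit_ols = TRUE)
score_recovery(network_from_model(fit), net)
#> <recovery_metrics> TP 15 FP 0 FN 0 | sens 1.000 prec 1.000 F 1.000
```

All 15 planted edges are recovered with no false positives: on noiseless
data the cascade regression identifies the true support exactly, which is
the package's basic correctness property. With noise, `stability_select()`
replaces the single fit and reports a selection frequency per edge.

The full pipeline (filtering, normalization, signatures, concordance,
inference, subnetwork, benchmark) runs from one configuration:

```r
run_pipeline(list(outdir = "run1", seed = 5, B = 100,
                  simulate = list(n_actors = 50, n_clusters = 3)))
```

writing TSV/SIF/GraphML/JSON artifacts for every stage under `run1/`.

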