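# phenolearn

Unsupervised phenotype discovery from noisy, sparse, irregularly timed
longitudinal laboratory data.

Electronic medical records hold years of lab values sampled whenever a
clinician ordered them — hours to years apart, densely during acute illness,
with assay noise. `phenolearn` turns such a sequence into a continuous
longitudinal probability density via Gaussian-process regression on warped
time, then learns an unsupervised feature representation of 30-day density
patches with a two-layer stacked sparse autoencoder whose reconstruction
loss is normalized by the density's own uncertainty. The learned encoder
rows act as data-driven trajectory phenotypes (ramps, spikes, edges) that
can be pooled per patient, classified, and embedded to look for
subpopulation structure. The demonstration analyte is serum uric acid
(mg/dl), whose longitudinal signatures differ between gout and acute
leukemia.

## The method in brief

For one sequence with warped observation times and standardized values
`y`, the posterior over a new measurement at time `t*` is Gaussian:

    mu(t*)     = k*' (K + c^2 I)^-1 y
    sigma^2(t*) = C(t*,t*) + c^2 - k*' (K + c^2 I)^-1 k*

with a rational-quadratic kernel by default and hyperparameters fitted by
the summed exact log marginal likelihood. Time intervals are warped as
`d' = a d^b` (b < 1) to exploit clinician-driven sampling: volatile periods
are sampled densely, so contracting long gaps brings sequences closer to
stationarity. Densities are evaluated daily with 15 days of padding.

The autoencoder minimizes, over 30-day standardized patches,

    J = mean reconstruction loss + (lambda/2) ||W||^2
        + beta * sum_j KL(rho || rho_hat_j)

with the layer-1 loss `0.5 * sum((x - x_hat)^2 / sigma^2)` (looser where
the density is uncertain) and plain squared error in layer 2. Per-sequence
vectors pool the per-feature maximum of activations rescaled by each
patch's pre-standardization sd, plus five summary statistics of those sds
(105 features at the default 100 hidden units). Elastic-net logistic
classifiers (mixing 0.95, 5-fold CV on the regularization path) and
empirical AUC with 95% BCa bootstrap intervals quantify what the features
capture, against an 11-feature expert-engineered comparator and a
sequence-mean baseline.

Because the original clinical data are not redistributable, the package
includes a calibrated synthetic cohort generator (gout-like and
leukemia-like uric acid dynamics with flares, treatment episodes, and
volatility-coupled sampling) so the entire pipeline is runnable and
testable from scratch.

## Worked example

```r
library(phenolearn)

# a labeled synthetic cohort, calibrated to the reference marginals
cohort <- generate_cohort(generator_config(n_gout = 60, n_leukemia = 60, seed = 1))
cohort_summary(cohort)
#>      label n_sequences n_values      min       q1   median       q3      max
#> 1     gout          60     2208 2.381057 6.614036 8.211566 9.920708 18.15870
#> 2 leukemia          60     1436 0.000000 2.553838 3.673355 4.993613 25.98842

# transform one sequence into a daily longitudinal density
std  <- standardize_global(cohort)
s    <- std$train[[1]]
w    <- list(list(times = warp_times(s$times), values = s$values))
hp   <- fit_hyperparameters(w, kernel = "rq")
dens <- posterior_density(s, hp)
dens
#> <longitudinal_density gout_0001> 612 daily points [-15, 596]

# learn features from 30-day patches and pool a 105-feature vector
patches <- extract_patches(dens, seed = 1)
layer   <- train_layer(patches, layer_config(30, n_hidden = 100), seed = 1)
acts    <- matrix(encode(patches$mu, layer), nrow = 100)
length(pool_sequence_features(acts, patches$patch_sd))
#> [1] 105

# empirical AUC with ties counted one half
auc_empirical(c(0.1, 0.4, 0.35, 0.8), factor(c("neg", "neg", "pos", "pos")))
#> [1] 0.75
```

The cohort summary shows the two pooled value distributions (the generator
is calibrated so that large cohorts give a gout median near 7.7 mg/dl and
a leukemia median near 4.2; at 60 sequences per label the medians wander a
few tenths around those targets). The density object holds the posterior
mean and predictive standard deviation per day, padded 15 days beyond the
observations. The pooled vector has `n_hidden + 5` entries: max-pooled
rescaled activations plus the mean/max/min/sd/range of the per-patch sds.

The full experiment — simulate, split 70/30, standardize, fit the kernel,
transform, train two layers, pool, train the four comparator classifiers,
report — runs behind one configuration object:

```r
res <- run_pipeline(pipeline_config(
  generator = generator_config(n_gout = 225, n_leukemia = 225),
  hidden_units = c(100L, 100L), test_fraction = 1/3, master_seed = 2024L),
  out_dir = "run")
res$report
#>     feature_set auc_train  auc_test    ci_low   ci_high n_train n_test
#> 1 layer1_pooled 0.9686986 0.9462251 0.9261237 0.9779942     300    150
#> 2 layer2_pooled 0.9502023 0.9303775 0.8930041 0.9679487     300    150
#> 3    engineered 0.9895958 0.9898504 0.9835714 0.9980862     300    150
#> 4 baseline_mean 0.9125873 0.9531695 0.9351654 0.9791852     300    150
```

Every intermediate artifact (sequences, standardization constants,
hyperparameters, densities, trained layers, feature tables, report,
manifest) is persisted as delimited text or JSON in the run directory, and
an identical configuration reproduces identical bytes. A thin command-line
front end over the same functions is installed at `inst/cli/phenolearn`
(subcommands `simulate`, `transform`, `train`, `run-all`, `report`).

See the methods vignette (`vignettes/phenotype-discovery.Rmd`) for the
model details, parameter meanings, the synthetic generator's design and
its limitations.

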