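# connvae

Single-subject anomaly detection on joint structural and functional brain
connectivity with a beta-normalized variational autoencoder.

## What it does, and for whom

Clinicians and neuroimaging researchers studying focal brain lesions (e.g.
gliomas) need to score *one* patient's connectome against a healthy norm
rather than compare groups. `connvae` implements a complete normative
pipeline over a 210-region parcellation (Schaefer-100 per hemisphere with
Yeo-17 network labels plus 10 subcortical regions, merged into 36
hemisphere-specific networks):

- **Preprocessing** — streamline counts are divided by the tractogram size
  (10 million by default, singleton streamlines zeroed), harmonized with FC
  through a data-driven power law `(w / w_max)^alpha` (alpha fitted by
  Kolmogorov–Smirnov grid search on the healthy training split), and both
  modalities are normalized with the inverse hyperbolic tangent before their
  upper triangles are concatenated.
- **Normative model** — a fully connected VAE (512–256–128 encoder, 8 latent
  dimensions, mirrored decoder, leaky ReLU) trained on healthy subjects with
  the objective `MSE + beta_NORM * KL`, where `beta_NORM = beta * M / N`
  scales the KL weight by latent size `M` over input size `N`. A
  transfer-learning step fine-tunes the model on a few minimally affected
  patients at a reduced learning rate.
- **Anomaly statistic** — masked (80th-percentile healthy edges), edgewise
  z-scored absolute reconstruction differences, averaged per parcel; a parcel
  is impaired when its score exceeds the healthy mean + 3 SD threshold, per
  modality (FC, SC, and integrated FC + SC).
- **Network metrics** — NAD (percentage of impaired parcels per network), GD
  (number of altered networks), OI (overlap between single-modality and
  integrated alterations), lesion-tissue stratification, and volume
  associations with Benjamini–Hochberg correction.
- **Synthetic cohorts** — a generator with known ground truth (network-block
  FC, FC-coupled sparse SC, proximal SC attenuation and distal FC shift for
  glioma subjects) so the entire pipeline is testable without imaging data.

## Worked example

```r
library(connvae)

spec <- simulation_spec(parcel_count = 60, networks_per_hemisphere = 5,
                        n_train = 60, n_val = 20, n_test = 20,
                        n_finetune_train = 7, n_finetune_val = 3,
                        n_patient_test = 10, seed = 11)
cohort <- simulate_cohort(spec)
config <- run_config(seed = 11, max_epochs = 300, patience = 300,
                     finetune_max_epochs = 60, finetune_patience = 60)
result <- run_pipeline(cohort, spec$scheme, config, out_dir = "run1")

result
#> <connvae_pipeline: 10 patients, thr FC=0.847 SC=0.908 FC+SC=0.758>
```

The thresholds are the healthy-test mean + 3 SD of the parcel-level
reconstruction-error scores, one per modality. Per-patient network metrics:

```r
result$metrics_table
#> # A tibble: 10 × 9
#>    subject_id gd_fc gd_sc gd_fcsc oi_fc oi_sc lesion_hemisphere volume_T volume_TO
#>  1 gl_test_01     4     8       7  75    75   right                 9000     12000
#>  2 gl_test_02     5     9       9 100    88.9 right                 9000     12000
#>  3 gl_test_03     5     9       8 100    77.8 left                  9000     12000
#>  ...
```

`gd_sc > gd_fc` in every patient: the simulated lesions attenuate SC on many
networks near the tumor while shifting FC in a single distal network — the
planted proximal-SC/distal-FC dissociation, which `cohort_summary(result$metrics)`
breaks down by tissue class. Volume associations (Pearson for GD, Spearman
for OI, BH-adjusted):

```r
result$associations
#> # A tibble: 10 × 7
#>    value   volume    method       n estimate p_value p_adjusted
#>  5 gd_fcsc volume_T  pearson     10   0.667   0.0353      0.128
#>  ...
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted model
(`autoplot(result$model)` plots the loss history), per-subject anomaly
results, and network metrics. Lower-level entry points
(`fit_civier_exponent()`, `train_vae()`, `fine_tune()`,
`build_healthy_reference()`, `detect_subject()`, `nad()`/`gd()`/
`overlap_index()`, ...) expose every stage separately; see the methods
vignette (`vignettes/connvae-methods.Rmd`) for the model, its assumptions
and the numerical choices.

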