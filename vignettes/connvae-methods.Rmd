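---
title: "Detecting single-subject connectome anomalies with a beta-normalized VAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-subject connectome anomalies with a beta-normalized VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connvae)
```

## The problem

Focal brain lesions such as gliomas reorganize brain connectivity far beyond
the visible tumor boundary. Group statistics cannot serve a single patient:
what is needed is a *normative* model — a description of what healthy joint
structural/functional connectivity looks like — against which one individual
connectome can be scored. `connvae` implements such a pipeline:

1. **Inputs.** Per subject, a functional connectivity matrix FC (Pearson
   correlations between regional BOLD time series) and a structural
   connectivity matrix SC (streamline counts from tractography divided by the
   tractogram size, with singleton-streamline entries zeroed as noise), both
   over a fixed 210-region parcellation: 100 Schaefer cortical parcels per
   hemisphere carrying the 17 Yeo network labels, plus 5 subcortical regions
   per hemisphere merged into one subcortical network — 36
   hemisphere-specific networks in total.
2. **Harmonization.** SC weights are heavy-tailed while FC lives in
   $[-1, 1]$; a data-driven power law $w \mapsto (w/w_{max})^{\alpha}$
   reshapes the SC distribution to resemble $|FC|$ so that one normalization
   can serve both. Both modalities then pass through the inverse hyperbolic
   tangent (the Fisher z transform for FC), and the strict upper triangles
   are concatenated into one model vector of length $2\binom{P}{2}$
   (43,890 at $P = 210$).
3. **Normative model.** A fully connected variational autoencoder
   (512–256–128 encoder, 8 latent dimensions, mirrored decoder, leaky-ReLU
   activations) is trained on healthy subjects to minimize
   $\mathrm{MSE} + \beta_{\mathrm{NORM}}\, \mathrm{KL}$, where
   $\beta_{\mathrm{NORM}} = \beta M / N$ rescales the KL weight by latent
   size $M$ over input size $N$ so that $\beta = 1$ means the same thing at
   any input size.
4. **Transfer learning.** The healthy-trained model is fine-tuned at a
   reduced learning rate on a few minimally affected patients, adapting it to
   the patient acquisition domain without erasing the healthy prior.
5. **Anomaly statistic.** Per patient and modality, the absolute difference
   between the original and reconstructed matrix is masked to the strongest
   healthy edges (those above the 80th percentile of the healthy group-mean
   weight distribution), z-scored edgewise against healthy-test statistics,
   and averaged over each parcel's retained edges. A parcel is *impaired*
   when its score exceeds the healthy threshold mean + 3 SD. The integrated
   FC + SC statistic sums the two normalized difference matrices over the
   mask union.
6. **Network metrics.** The network alteration degree
   $\mathrm{NAD}_n = \tfrac{100}{K}\sum_{k=1}^{K}\mathrm{impaired}_k$ is the
   percentage of impaired parcels in network $n$; global disruption
   $\mathrm{GD} = \#\{n : \mathrm{NAD}_n > 0\}$ counts altered networks; the
   overlap index $\mathrm{OI} = 100\,|S \cap I|/|S|$ measures how much of a
   single modality's altered set $S$ reappears in the integrated set $I$.
   Networks are stratified by lesion overlap (tumor > edema > healthy
   precedence), and GD/OI are correlated with tumor (T) and lesion (T + O)
   volumes (Pearson for GD, Spearman for OI, Benjamini–Hochberg corrected).

## The synthetic cohort

Real multimodal cohorts of this kind are not redistributable, so the package
ships a generator whose output exercises every pipeline stage with known
ground truth:

- healthy FC is a network-block template (within-network mean 0.6,
  between-network 0.1, edgewise spread 0.05) plus per-subject symmetric
  Gaussian noise (SD 0.05), clipped inside $(-1, 1)$;
- SC is sparse (expected density 0.25) with edge presence probability
  increasing in the FC rank (structure–function coupling) and log-normal
  streamline counts (meanlog $\log 2000$, sdlog 1), jittered multiplicatively
  per subject (log-SD 0.2);
- glioma subjects grow a tumor from a random seed parcel on a
  parcel-adjacency graph (same-network adjacency plus a ring ordering per
  hemisphere — a geometry-free stand-in for spatial neighborhood, since no
  atlas volumes are involved), with an edema ring beyond it. SC edges
  incident to tumor parcels are multiplied by `sc_effect` (default 0.3),
  while FC edges of a distal contralateral network are shifted by
  `fc_effect_distal` (default +0.15) — reproducing the characteristic
  dissociation that structural damage concentrates near the lesion while
  functional changes appear at distance;
- fine-tuning patients use deliberately milder effects (`sc_effect` 0.85,
  FC shift 0.03), matching the transfer-learning requirement of minimally
  abnormal adaptation subjects;
- lesion "volumes" are parcel counts times a nominal 1500 mm³; only their
  ordering is meaningful, which is all the volume-association tests use.

The default subject counts mirror the reference design (87/37/31 healthy
train/validation/test, 7 + 3 fine-tuning patients, 31 test patients). No
quantitative literature values exist for glioma-induced connectivity effect
sizes, so the defaults above were chosen once for clear detectability and
should be treated as arbitrary simulation settings, not biology. The
generator makes no attempt at realistic hemodynamics, tractography error
models, spatial geometry, or site effects — so green tests demonstrate the
pipeline's statistical machinery, not clinical performance.

```{r example}
spec <- simulation_spec(parcel_count = 60, networks_per_hemisphere = 5,
                        n_train = 60, n_val = 20, n_test = 20,
                        n_finetune_train = 7, n_finetune_val = 3,
                        n_patient_test = 10, seed = 11)
cohort <- simulate_cohort(spec)
config <- run_config(seed = 11, max_epochs = 300, patience = 300,
                     finetune_max_epochs = 60, finetune_patience = 60)
result <- run_pipeline(cohort, spec$scheme, config, out_dir = "run1")
result$metrics_table
autoplot(result$model)
```

## Problem sizes

The package's own test suite and the bundled acceptance script run the full
pipeline at 60 parcels (5 networks per hemisphere), 60/20/20 healthy splits,
7 + 3 fine-tuning and 10 test patients, training for 300 epochs — a
configuration chosen so a complete run takes minutes on one CPU while still
exhibiting every qualitative property of the full-size setting (block
structure, sparsity, lesion dissociation, threshold calibration). The
full 210-parcel, 2000-epoch configuration is the package default and runs
unchanged, just longer.

## Numerical and design choices

Where the method leaves details open, the package fixes them as follows.

- **Civier exponent fit.** $\alpha$ minimizes the two-sample
  Kolmogorov–Smirnov distance between transformed SC and $|FC|$ over the grid
  $0.01, 0.02, \dots, 1.00$, using the *pooled* nonzero SC and FC weights of
  the healthy training split (pooling subjects rather than fitting the group
  mean keeps subject-level tail behavior in the fit). The fitted $\alpha$,
  the training maximum $w_{max}$ and the scale are frozen and reused for
  every other subject; patient weights above $w_{max}$ are capped at the
  transform ceiling $1 - \varepsilon$.
- **One normalization step.** FC is not Fisher-z transformed separately
  before the shared inverse-hyperbolic-tangent step — artanh *is* the Fisher
  z transform, so the map is applied once per modality, with transformed SC
  first scaled into $[0, 1-\varepsilon]$ ($\varepsilon = 10^{-6}$) so both
  blocks share the codomain.
- **Upper-triangle order.** Row-major over pairs $i < j$, fixed package-wide.
- **VAE details.** Leaky-ReLU slope 0.01; the final decoder layer is linear
  so artanh-domain targets are reachable, and the hyperbolic tangent is
  applied only when rebuilding connectivity matrices, where reconstructed SC
  values below zero are clamped to 0 (SC stays in the transformed domain).
  Training draws one reparameterized latent sample per input; inference
  decodes the latent mean and never samples. Losses are averaged over batch
  *and* features, which is what makes $\beta M/N$ the per-feature KL weight.
  Early stopping monitors the total validation loss (reconstruction + KL)
  and restores the best-validation weights.
- **Transfer learning.** The full network is fine-tuned at learning rate
  $10^{-4}$ (an encoder-freezing option exists but is off by default — with
  only a handful of adaptation subjects, the early-stopping rule is the
  effective regularizer, and it will keep the healthy weights whenever
  fine-tuning does not actually improve the patient validation loss).
- **Difference normalization.** The exact ad-hoc normalization of the
  difference matrices is concretized as a per-edge z-score against the
  healthy-test mean and SD, with a pooled-SD fallback for degenerate edges;
  it is isolated in `normalize_difference()` so an alternative can be swapped
  in one place.
- **Parcel aggregation.** A parcel's score is the *mean* of its
  mask-retained normalized differences (a sum would make parcels with more
  retained edges look more anomalous); parcels with no retained edges carry
  an `NA` sentinel and are never flagged.
- **Thresholds.** One pooled scalar threshold per modality (parcels ×
  healthy-test subjects pooled), mean + 3 SD, strict exceedance. The FC + SC
  threshold is built from healthy FC + SC parcel scores by the same rule.
- **Percentile masks** use signed FC weights (retaining the strongest
  positive connections) and all upper-triangle SC entries including zeros;
  both choices are configurable in spirit but fixed here for
  reproducibility.
- **Tissue stratification** counts a network as tumor/edema class when *any*
  of its parcels overlaps that tissue (threshold 0, configurable); whether
  only the network's impaired parcels should count is ambiguous, and the
  any-parcel rule was chosen as the more conservative attribution.
- **Cohort summaries.** `cohort_summary()` reports, per network, tissue class
  and exclusive modality combination, both the percentage of all subjects
  (`pct_subjects`, comparable to per-network spider plots) and the percentage
  of subjects *for whom that network has that tissue class*
  (`pct_within_class`). `tissue_frequency()` aggregates the latter view per
  class and modality: because lesions sit at different parcels in different
  subjects, a network is tumor-class in only a few subjects, and only the
  class-conditional frequency makes the proximal-SC/distal-FC dissociation
  visible without class-size bias.
- **Multiple comparisons.** Benjamini–Hochberg across all tests requested in
  one call.
- **Determinism.** Every random stage derives an independent sub-seed from
  the run seed; reruns are bitwise identical, and the pipeline manifest
  records seeds, thresholds, output checksums and which stage touched which
  subject (patient test data are provably untouched before detection).

## Limitations

- The generator's simplifications mean calibration numbers (e.g. the ~1%
  healthy flag rate at the 3 SD threshold) translate to real data only
  insofar as real per-edge reconstruction errors are approximately Gaussian.
- With few fine-tuning subjects the transfer-learning stage may legitimately
  be a no-op (early stopping keeps the healthy weights); this is by design
  but means the ablation (`skip_finetune = TRUE`) can be indistinguishable
  on easy synthetic cohorts.
- Excluded-parcel handling (necrosis-destroyed regions) is supported as
  sentinel rows and an optional per-subject exclusion list, but no parcels
  are dropped by default.
- Reconstruction-probability or latent-distance anomaly scores are out of
  scope; the statistic is reconstruction error only, as is the exploratory
  latent-space clustering.
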