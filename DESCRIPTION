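Package: connvae
Title: Multimodal Connectome Anomaly Detection with a Beta-Normalized
    Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-subject anomaly detection on joint functional (FC) and
    structural (SC) brain connectivity matrices. Implements power-law
    harmonization of streamline-count connectomes, inverse hyperbolic tangent
    normalization, a beta-normalized variational autoencoder trained on
    healthy connectomes with transfer learning to a patient domain,
    reconstruction-error anomaly statistics against a healthy reference
    (80th-percentile edge masks, per-edge z-scoring, mean + 3 SD thresholds),
    and network-level alteration metrics (network alteration degree, global
    disruption, overlap index) with lesion-tissue stratification and
    volume-association tests. Ships a synthetic cohort generator with known
    ground truth so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
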