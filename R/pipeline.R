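#' Run configuration
#'
#' Bundles every tunable of the end-to-end pipeline: the anomaly-statistic
#' settings (80th-percentile masks, mean + 3 SD thresholds, 10-million-tract
#' normalization) and the VAE training hyperparameters.
#'
#' @param seed Base seed; every random stage derives its own stream from it.
#' @param percentile_cutoff Mask percentile in (0, 100).
#' @param threshold_sd_multiplier SD multiplier of the threshold rule (> 0).
#' @param total_streamlines Tractogram size for SC normalization.
#' @param epsilon_clip Clipping margin of the artanh normalization.
#' @param encoder_widths,latent_dim,beta,learning_rate,batch_size,max_epochs,patience,finetune_lr,freeze_encoder
#'   VAE settings, see [vae_config()].
#' @param finetune_max_epochs,finetune_patience Optional overrides of the
#'   epoch budget for the transfer-learning stage (defaults: same as
#'   training).
#' @return A list of class `connvae_run_config`.
#' @export
run_config <- function(seed = 1,
                       percentile_cutoff = 80,
                       threshold_sd_multiplier = 3,
                       total_streamlines = 1e7,
                       epsilon_clip = 1e-6,
                       encoder_widths = c(512, 256, 128),
                       latent_dim = 8, beta = 1,
                       learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 2000, patience = 750,
                       finetune_lr = 1e-4,
                       finetune_max_epochs = NULL, finetune_patience = NULL,
                       freeze_encoder = FALSE) {
  stopifnot(percentile_cutoff > 0, percentile_cutoff < 100,
            threshold_sd_multiplier > 0, total_streamlines > 0)
  structure(list(seed = seed, percentile_cutoff = percentile_cutoff,
                 threshold_sd_multiplier = threshold_sd_multiplier,
                 total_streamlines = total_streamlines,
                 epsilon_clip = epsilon_clip,
                 encoder_widths = encoder_widths, latent_dim = latent_dim,
                 beta = beta, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, finetune_lr = finetune_lr,
                 finetune_max_epochs = finetune_max_epochs,
                 finetune_patience = finetune_patience,
                 freeze_encoder = freeze_encoder),
            class = "connvae_run_config")
}

# subject loader with per-stage access logging (supports the leakage guard)
make_subject_loader <- function(cohort) {
  from_sim <- inherits(cohort, "connvae_sim_cohort")
  records <- if (from_sim) cohort$records else cohort
  access <- new.env(parent = emptyenv())
  access$log <- tibble(subject_id = character(), stage = character())
  load_subject <- function(sid, stage) {
    access$log <- bind_rows(access$log,
                            tibble(subject_id = sid, stage = stage))
    if (from_sim) {
      s <- cohort$subjects[[sid]]
      list(fc = s$fc, sc_counts = s$sc_counts)
    } else {
      i <- match(sid, records$subject_id)
      list(fc = read_conn_matrix(records$fc_path[i], "FC"),
           sc_counts = read_conn_matrix(records$sc_path[i], "SC_counts"))
    }
  }
  list(records = records, load = load_subject, access = access)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full anomaly-detection pipeline
#'
#' Orchestrates preprocess (Civier fit on the pooled healthy training split,
#' normalization, model vectors), VAE training on healthy train/validation,
#' transfer learning on the patient fine-tuning splits, healthy-reference
#' construction on the healthy test split, per-patient anomaly detection, and
#' network metrics with volume-association tests. Re-running with the same
#' seed reproduces all numeric outputs exactly. Patient test matrices are not
#' read before the detection stage.
#'
#' @param cohort A `connvae_sim_cohort` (in-memory) or a cohort tibble from
#'   [read_cohort_manifest()] (file-backed).
#' @param scheme A `connvae_parcellation` matching the matrices.
#' @param config A `connvae_run_config`.
#' @param out_dir Optional directory; when given, tables and a provenance
#'   manifest (seeds, thresholds, checksums, per-stage subject access) are
#'   written there.
#' @param skip_finetune If `TRUE`, detection uses the healthy-trained model
#'   directly (the transfer-learning ablation).
#' @return A list of class `connvae_pipeline`: `model`, `reference`,
#'   `anomalies`, `impaired_matrix`, `metrics`, `metrics_table`, `summary`,
#'   `associations`, `norm_params`, `manifest`.
#' @export
run_pipeline <- function(cohort, scheme, config = run_config(),
                         out_dir = NULL, skip_finetune = FALSE) {
  loader <- make_subject_loader(cohort)
  records <- loader$records
  p <- n_parcels(scheme)
  split_ids <- function(co, sp)
    records$subject_id[records$cohort == co & records$split == sp]
  ids <- list(
    train = split_ids("healthy", "train"),
    val = split_ids("healthy", "validation"),
    test = split_ids("healthy", "test"),
    ft_train = split_ids("glioma", "finetune_train"),
    ft_val = split_ids("glioma", "finetune_val"),
    patient_test = split_ids("glioma", "test")
  )
  for (nm in c("train", "val", "test")) {
    if (!length(ids[[nm]])) {
      abort(sprintf("cohort lacks healthy %s subjects", nm),
            class = "connvae_format_error")
    }
  }

  # -- preprocess: fit normalization on the pooled healthy training split
  train_raw <- lapply(ids$train, loader$load, stage = "preprocess")
  names(train_raw) <- ids$train
  train_sc <- lapply(train_raw, function(s)
    normalize_sc_counts(s$sc_counts, config$total_streamlines))
  sc_pool <- unlist(lapply(train_sc, function(m) {
    v <- vectorize_upper(m); v[!is.na(v) & v > 0]
  }))
  fc_pool <- unlist(lapply(train_raw, function(s) {
    v <- vectorize_upper(s$fc); v[!is.na(v)]
  }))
  params <- fit_civier_exponent(sc_pool, fc_pool,
                                epsilon_clip = config$epsilon_clip)

  prep <- function(sid, stage) {
    s <- loader$load(sid, stage)
    preprocess_subject(s$fc, s$sc_counts, params, config$total_streamlines)
  }
  prep_split <- function(sids, stage) {
    out <- lapply(sids, prep, stage = stage)
    names(out) <- sids
    out
  }
  train_prep <- lapply(names(train_raw), function(sid)
    preprocess_subject(train_raw[[sid]]$fc, train_raw[[sid]]$sc_counts,
                       params, config$total_streamlines))
  names(train_prep) <- names(train_raw)
  val_prep <- prep_split(ids$val, "preprocess")

  as_matrix <- function(prep_list)
    do.call(rbind, lapply(prep_list, `[[`, "model_vector"))

  # -- train on healthy subjects
  vcfg <- vae_config(
    input_length = p * (p - 1),
    latent_dim = config$latent_dim, encoder_widths = config$encoder_widths,
    beta = config$beta, learning_rate = config$learning_rate,
    batch_size = config$batch_size, max_epochs = config$max_epochs,
    patience = config$patience, finetune_lr = config$finetune_lr,
    freeze_encoder = config$freeze_encoder,
    seed = derive_seed(config$seed, "vae"))
  model <- train_vae(as_matrix(train_prep), as_matrix(val_prep), vcfg)

  # -- transfer learning on the fine-tuning patients
  if (!skip_finetune && length(ids$ft_train) && length(ids$ft_val)) {
    ft_train_prep <- prep_split(ids$ft_train, "finetune")
    ft_val_prep <- prep_split(ids$ft_val, "finetune")
    ft_override <- list()
    if (!is.null(config$finetune_max_epochs)) {
      ft_override$max_epochs <- config$finetune_max_epochs
    }
    if (!is.null(config$finetune_patience)) {
      ft_override$patience <- config$finetune_patience
    }
    model <- fine_tune(model, as_matrix(ft_train_prep),
                       as_matrix(ft_val_prep), config_override = ft_override)
  }

  # -- healthy reference from the held-out healthy test split
  test_prep <- prep_split(ids$test, "detect_reference")
  reference <- build_healthy_reference(
    model, test_prep,
    percentile_cutoff = config$percentile_cutoff,
    threshold_sd_multiplier = config$threshold_sd_multiplier)

  # -- patient detection (first stage allowed to touch patient test data)
  anomalies <- list()
  for (sid in ids$patient_test) {
    anomalies[[sid]] <- detect_subject(model, reference,
                                       prep(sid, "detect"), subject_id = sid)
  }
  impaired_matrix <- if (length(anomalies)) {
    stack_cohort(lapply(anomalies, function(a) a$impaired$FCSC))
  } else NULL

  # -- network metrics
  metrics <- list(); metrics_table <- NULL; summary_tbl <- NULL
  associations <- NULL
  if (length(anomalies)) {
    metrics <- lapply(ids$patient_test, function(sid)
      network_metrics(anomalies[[sid]],
                      records[records$subject_id == sid, ], scheme))
    names(metrics) <- ids$patient_test
    metrics_table <- bind_rows(lapply(metrics, glance))
    summary_tbl <- cohort_summary(metrics)
    if (nrow(metrics_table) >= 3L) {
      assoc_gd <- associate_with_volume(
        metrics_table, c("gd_fc", "gd_sc", "gd_fcsc"),
        c("volume_T", "volume_TO"), method = "pearson")
      oi_ok <- colSums(is.finite(as.matrix(
        metrics_table[, c("oi_fc", "oi_sc")]))) >= 3L
      assoc_oi <- if (any(oi_ok)) {
        associate_with_volume(metrics_table,
                              c("oi_fc", "oi_sc")[oi_ok],
                              c("volume_T", "volume_TO"),
                              method = "spearman")
      } else NULL
      associations <- bind_rows(assoc_gd, assoc_oi)
      associations$p_adjusted <- p.adjust(associations$p_value, method = "BH")
    }
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    norm_params = unclass(params),
    thresholds = reference$thr,
    splits = lapply(ids, as.character),
    subject_access = loader$access$log,
    skip_finetune = skip_finetune,
    model = as.list(glance(model))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    if (!is.null(impaired_matrix)) {
      imp <- as.data.frame(impaired_matrix * 1L)
      names(imp) <- ids$patient_test
      imp <- cbind(parcel_id = scheme$parcel_id, imp)
      files <- c(files,
                 write_tsv(imp, file.path(out_dir, "impaired_parcels.tsv")))
    }
    files <- c(files, write_tsv(model$history,
                                file.path(out_dir, "training_history.tsv")))
    if (!is.null(metrics_table)) {
      files <- c(files, write_tsv(metrics_table,
                                  file.path(out_dir, "network_metrics.tsv")))
    }
    if (!is.null(summary_tbl)) {
      files <- c(files, write_tsv(summary_tbl,
                                  file.path(out_dir, "cohort_summary.tsv")))
    }
    if (!is.null(associations)) {
      files <- c(files, write_tsv(associations,
                                  file.path(out_dir, "volume_associations.tsv")))
    }
    manifest$output_checksums <- as.list(tools::md5sum(files))
    manifest$subject_access <- as.data.frame(manifest$subject_access)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  structure(list(model = model, reference = reference, anomalies = anomalies,
                 impaired_matrix = impaired_matrix, metrics = metrics,
                 metrics_table = metrics_table, summary = summary_tbl,
                 associations = associations, norm_params = params,
                 manifest = manifest),
            class = "connvae_pipeline")
}

#' @export
print.connvae_pipeline <- function(x, ...) {
  cat(sprintf(
    "<connvae_pipeline: %d patients, thr FC=%.3f SC=%.3f FC+SC=%.3f>\n",
    length(x$anomalies), x$reference$thr$FC, x$reference$thr$SC,
    x$reference$thr$FCSC))
  invisible(x)
}
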