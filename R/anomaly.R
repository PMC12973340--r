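#' Percentile mask of a group-mean connectivity matrix
#'
#' Retains the edges whose upper-triangle weight is strictly greater than the
#' linear-interpolation percentile (type-7 quantile) of all upper-triangle
#' entries, i.e. the strongest ~20% of connections at the default cutoff of
#' 80. The returned mask is a symmetric logical matrix with a `FALSE`
#' diagonal.
#'
#' @param mean_matrix Square symmetric matrix (group mean).
#' @param cutoff Percentile in (0, 100).
#' @return Logical `P x P` mask.
#' @export
percentile_mask <- function(mean_matrix, cutoff = 80) {
  stopifnot(cutoff > 0, cutoff < 100)
  m <- unclass(mean_matrix)
  ut <- vectorize_upper(m)
  q <- quantile(ut, cutoff / 100, type = 7, names = FALSE, na.rm = TRUE)
  if (diff(range(ut, na.rm = TRUE)) == 0) {
    warn("all edges equal: percentile mask is empty")
  }
  mask <- !is.na(m) & m > q
  diag(mask) <- FALSE
  mask
}

#' Masked absolute difference between original and reconstruction
#'
#' @param orig,recon Same-dimension square matrices (SC comparisons must be
#'   made in the power-transformed domain).
#' @param mask Logical mask; unmasked edges are zero in the output.
#' @return Non-negative matrix of masked absolute differences.
#' @export
difference_matrix <- function(orig, recon, mask) {
  orig <- unclass(orig); recon <- unclass(recon)
  if (!all(dim(orig) == dim(recon)) || !all(dim(orig) == dim(mask))) {
    abort("shape mismatch in difference_matrix",
          class = "connvae_format_error")
  }
  d <- abs(orig - recon)
  d[!mask] <- 0
  d[is.na(d)] <- 0
  d
}

# per-edge mean/SD of masked absolute differences across healthy subjects
edge_statistics <- function(diff_list, mask) {
  arr <- simplify2array(diff_list)
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), sd)
  pooled <- sd(unlist(lapply(diff_list, function(d) d[mask])))
  list(mean = mean_m, sd = sd_m, pooled_sd = pooled, mask = mask)
}

#' Z-score a difference matrix against healthy per-edge statistics
#'
#' Per masked edge: `(diff - healthy mean) / healthy SD`. Edges whose healthy
#' SD is numerically zero fall back to the pooled modality SD so the score
#' stays finite. Values may be negative (smaller error than the healthy
#' mean).
#'
#' @param diff Masked absolute-difference matrix.
#' @param edge_stats Per-edge statistics from the healthy reference.
#' @return Normalized difference matrix (zero outside the mask).
#' @export
normalize_difference <- function(diff, edge_stats) {
  mask <- edge_stats$mask
  if (!all(dim(diff) == dim(mask))) {
    abort("shape mismatch in normalize_difference",
          class = "connvae_format_error")
  }
  sdm <- edge_stats$sd
  if (any(is.na(sdm[mask]))) {
    abort("healthy statistics missing for a masked edge",
          class = "connvae_format_error")
  }
  sdm[sdm < 1e-12] <- edge_stats$pooled_sd
  out <- (diff - edge_stats$mean) / sdm
  out[!mask] <- 0
  out
}

#' Integrate normalized FC and SC difference matrices
#'
#' Elementwise sum; the support is the union of the two masks (an edge
#' retained by only one modality contributes only that modality's value).
#'
#' @param norm_diff_fc,norm_diff_sc Normalized difference matrices.
#' @return The FC + SC difference matrix.
#' @export
integrate_modalities <- function(norm_diff_fc, norm_diff_sc) {
  if (!all(dim(norm_diff_fc) == dim(norm_diff_sc))) {
    abort("shape mismatch in integrate_modalities",
          class = "connvae_format_error")
  }
  norm_diff_fc + norm_diff_sc
}

#' Parcel-level anomaly scores
#'
#' For each parcel, the mean of the normalized difference over that parcel's
#' mask-retained edges (its row in the symmetrized masked matrix). Parcels
#' with no retained edges get the `NA` sentinel and are excluded downstream.
#'
#' @param norm_diff Normalized difference matrix.
#' @param mask Logical mask giving each parcel's retained edges.
#' @return Numeric vector of length `P`.
#' @export
parcel_scores <- function(norm_diff, mask) {
  p <- nrow(mask)
  vapply(seq_len(p), function(i) {
    j <- mask[i, ]
    if (!any(j)) NA_real_ else mean(norm_diff[i, j])
  }, numeric(1))
}

#' Pooled mean + k*SD anomaly threshold
#'
#' The modality-specific threshold is the mean plus `multiplier` sample
#' standard deviations of all pooled healthy-test parcel scores.
#'
#' @param scores Numeric vector (healthy-test parcel scores, pooled over
#'   parcels and subjects; `NA` sentinels ignored).
#' @param multiplier SD multiplier (3 by default).
#' @return Scalar threshold.
#' @export
threshold_mean_3sd <- function(scores, multiplier = 3) {
  stopifnot(multiplier > 0)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) {
    abort("need at least 2 finite scores", class = "connvae_format_error")
  }
  mean(scores) + multiplier * sd(scores)
}

#' Flag impaired parcels
#'
#' A parcel is impaired when its score strictly exceeds the threshold;
#' sentinel (`NA`) scores are never flagged.
#'
#' @param scores Parcel score vector.
#' @param thr Scalar threshold.
#' @return Logical vector of length `P`.
#' @export
flag_impaired <- function(scores, thr) {
  stopifnot(is.finite(thr))
  out <- !is.na(scores) & scores > thr
  out
}

#' Stack per-subject impaired vectors into a parcel x subject matrix
#'
#' @param impaired_list Named list of logical length-P vectors; column order
#'   follows the list order.
#' @return Logical `P x S` matrix.
#' @export
stack_cohort <- function(impaired_list) {
  lens <- lengths(impaired_list)
  if (length(unique(lens)) != 1L) {
    abort("impaired vectors have differing lengths",
          class = "connvae_format_error")
  }
  do.call(cbind, impaired_list)
}

#' Build the healthy reference for anomaly detection
#'
#' From the healthy test split: group-mean FC and (transformed) SC matrices,
#' 80th-percentile edge masks, per-edge error statistics of the masked
#' absolute reconstruction differences, per-subject normalized parcel scores,
#' and the pooled mean + 3 SD thresholds for FC, SC and the integrated
#' FC + SC modality.
#'
#' @param model Trained `connvae_vae` (healthy-trained).
#' @param healthy_test Named list of preprocessed subjects (each as returned
#'   by [preprocess_subject()]).
#' @param percentile_cutoff Mask percentile.
#' @param threshold_sd_multiplier SD multiplier of the threshold rule.
#' @return A list of class `connvae_reference`.
#' @export
build_healthy_reference <- function(model, healthy_test,
                                    percentile_cutoff = 80,
                                    threshold_sd_multiplier = 3) {
  stopifnot(length(healthy_test) >= 2L)
  p <- nrow(healthy_test[[1L]]$fc)
  fc_orig <- lapply(healthy_test, function(s) unclass(s$fc))
  sc_orig <- lapply(healthy_test, function(s) unclass(s$sc_transformed))
  mean_fc <- Reduce(`+`, fc_orig) / length(fc_orig)
  mean_sc <- Reduce(`+`, sc_orig) / length(sc_orig)
  mask_fc <- percentile_mask(mean_fc, percentile_cutoff)
  mask_sc <- percentile_mask(mean_sc, percentile_cutoff)

  recons <- lapply(healthy_test, function(s)
    reconstruct_subject(model, s$model_vector, p))
  diffs_fc <- Map(function(s, r)
    difference_matrix(unclass(s$fc), unclass(r$fc_recon), mask_fc),
    healthy_test, recons)
  diffs_sc <- Map(function(s, r)
    difference_matrix(unclass(s$sc_transformed), unclass(r$sc_recon), mask_sc),
    healthy_test, recons)
  stats_fc <- edge_statistics(diffs_fc, mask_fc)
  stats_sc <- edge_statistics(diffs_sc, mask_sc)

  norm_fc <- lapply(diffs_fc, normalize_difference, edge_stats = stats_fc)
  norm_sc <- lapply(diffs_sc, normalize_difference, edge_stats = stats_sc)
  mask_union <- mask_fc | mask_sc
  scores_fc <- lapply(norm_fc, parcel_scores, mask = mask_fc)
  scores_sc <- lapply(norm_sc, parcel_scores, mask = mask_sc)
  scores_fcsc <- Map(function(f, s)
    parcel_scores(integrate_modalities(f, s), mask_union), norm_fc, norm_sc)

  thr <- list(
    FC = threshold_mean_3sd(unlist(scores_fc), threshold_sd_multiplier),
    SC = threshold_mean_3sd(unlist(scores_sc), threshold_sd_multiplier),
    FCSC = threshold_mean_3sd(unlist(scores_fcsc), threshold_sd_multiplier)
  )
  structure(list(
    mean_fc = mean_fc, mean_sc = mean_sc,
    mask_fc = mask_fc, mask_sc = mask_sc, mask_union = mask_union,
    edge_stats_fc = stats_fc, edge_stats_sc = stats_sc,
    healthy_scores = list(FC = scores_fc, SC = scores_sc,
                          FCSC = scores_fcsc),
    thr = thr,
    percentile_cutoff = percentile_cutoff,
    threshold_sd_multiplier = threshold_sd_multiplier,
    n_subjects = length(healthy_test)
  ), class = "connvae_reference")
}

#' @export
print.connvae_reference <- function(x, ...) {
  cat(sprintf(
    "<connvae_reference: %d healthy subjects, thr FC=%.3f SC=%.3f FC+SC=%.3f>\n",
    x$n_subjects, x$thr$FC, x$thr$SC, x$thr$FCSC))
  invisible(x)
}

#' Detect impaired parcels in one subject
#'
#' Reconstructs the subject with the (fine-tuned) model, forms masked
#' normalized absolute-difference matrices for FC and SC, their FC + SC sum,
#' parcel scores, and impaired flags against the healthy thresholds.
#'
#' @param model Trained `connvae_vae`.
#' @param reference A `connvae_reference`.
#' @param subject Preprocessed subject (from [preprocess_subject()]).
#' @param subject_id Identifier stored in the result.
#' @return A list of class `connvae_anomaly` with `diff` (normalized
#'   difference matrices), `scores` and `impaired` per modality.
#' @export
detect_subject <- function(model, reference, subject,
                           subject_id = NA_character_) {
  p <- nrow(subject$fc)
  recon <- reconstruct_subject(model, subject$model_vector, p)
  d_fc <- difference_matrix(unclass(subject$fc), unclass(recon$fc_recon),
                            reference$mask_fc)
  d_sc <- difference_matrix(unclass(subject$sc_transformed),
                            unclass(recon$sc_recon), reference$mask_sc)
  n_fc <- normalize_difference(d_fc, reference$edge_stats_fc)
  n_sc <- normalize_difference(d_sc, reference$edge_stats_sc)
  n_fcsc <- integrate_modalities(n_fc, n_sc)
  scores <- list(
    FC = parcel_scores(n_fc, reference$mask_fc),
    SC = parcel_scores(n_sc, reference$mask_sc),
    FCSC = parcel_scores(n_fcsc, reference$mask_union)
  )
  impaired <- list(
    FC = flag_impaired(scores$FC, reference$thr$FC),
    SC = flag_impaired(scores$SC, reference$thr$SC),
    FCSC = flag_impaired(scores$FCSC, reference$thr$FCSC)
  )
  structure(list(subject_id = subject_id,
                 diff = list(FC = n_fc, SC = n_sc, FCSC = n_fcsc),
                 scores = scores, impaired = impaired,
                 recon = recon),
            class = "connvae_anomaly")
}

#' @export
print.connvae_anomaly <- function(x, ...) {
  cat(sprintf("<connvae_anomaly %s: impaired FC=%d SC=%d FC+SC=%d of %d>\n",
              x$subject_id, sum(x$impaired$FC), sum(x$impaired$SC),
              sum(x$impaired$FCSC), length(x$impaired$FC)))
  invisible(x)
}

#' Tidy parcel-level anomaly table
#' @param x A `connvae_anomaly`.
#' @param scheme Optional parcellation to attach parcel metadata.
#' @param ... Unused.
#' @return Long tibble with `parcel_id`, `modality`, `score`, `impaired`.
#' @method tidy connvae_anomaly
#' @export
tidy.connvae_anomaly <- function(x, scheme = NULL, ...) {
  p <- length(x$scores$FC)
  ids <- if (!is.null(scheme)) scheme$parcel_id else sprintf("p%03d", seq_len(p))
  out <- bind_rows(lapply(c("FC", "SC", "FCSC"), function(mod) tibble(
    subject_id = x$subject_id, parcel_id = ids, modality = mod,
    score = x$scores[[mod]], impaired = x$impaired[[mod]])))
  if (!is.null(scheme)) {
    out <- left_join(out, as_tibble(scheme), by = "parcel_id")
  }
  out
}

#' Heatmap of a subject's normalized difference matrix
#' @param object A `connvae_anomaly`.
#' @param modality `"FC"`, `"SC"` or `"FCSC"`.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @method autoplot connvae_anomaly
#' @export
autoplot.connvae_anomaly <- function(object, modality = "FCSC", ...) {
  m <- object$diff[[modality]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "z",
                  title = sprintf("%s normalized difference (%s)",
                                  modality, object$subject_id)) +
    ggplot2::theme_minimal()
}
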