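#' Network alteration degree (NAD)
#'
#' For each hemisphere-specific network `n` with `K` parcels, the percentage
#' of its parcels flagged impaired: `NAD_n = 100 / K * sum(impaired)`.
#'
#' @param impaired Logical vector, one flag per parcel (scheme order).
#' @param scheme A `connvae_parcellation`.
#' @return Tibble with `network_key`, `hemisphere`, `network`, `K`,
#'   `n_impaired`, `nad`.
#' @export
nad <- function(impaired, scheme) {
  if (length(impaired) != n_parcels(scheme)) {
    abort("impaired vector length does not match scheme",
          class = "connvae_format_error")
  }
  tibble(network_key = scheme$network_key, impaired = as.logical(impaired)) |>
    group_by(.data$network_key) |>
    summarise(K = dplyr::n(), n_impaired = sum(.data$impaired),
              .groups = "drop") |>
    mutate(nad = 100 * .data$n_impaired / .data$K) |>
    left_join(networks(scheme)[, c("network_key", "hemisphere", "network")],
              by = "network_key") |>
    select("network_key", "hemisphere", "network", "K", "n_impaired", "nad") |>
    arrange(.data$network_key)
}

#' Global disruption (GD)
#'
#' The number of networks with NAD strictly greater than zero. The comparison
#' is made on the integer impaired-parcel count, so no floating-point
#' percentage is involved.
#'
#' @param nad_table Output of [nad()].
#' @return Integer count of altered networks.
#' @export
gd <- function(nad_table) {
  sum(nad_table$n_impaired > 0L)
}

#' Overlap index (OI)
#'
#' Percentage of the single-modality altered networks that are also altered
#' in the integrated FC + SC modality:
#' `OI = 100 * |single intersect integrated| / |single|`. Undefined (`NA`)
#' when the single-modality set is empty.
#'
#' @param single_networks Character vector of network keys altered in the
#'   single modality.
#' @param integrated_networks Network keys altered in FC + SC.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
overlap_index <- function(single_networks, integrated_networks) {
  if (length(single_networks) == 0L) return(NA_real_)
  100 * length(intersect(single_networks, integrated_networks)) /
    length(single_networks)
}

#' Classify networks by lesioned tissue overlap
#'
#' A network is `tumor`-class when any of its parcels overlaps the tumor core
#' beyond `overlap_threshold`, else `edema`-class by the same rule on the
#' edema fractions, else `healthy` (precedence tumor > edema > healthy).
#'
#' @param record One-row cohort tibble (a `SubjectRecord`).
#' @param scheme A `connvae_parcellation`.
#' @param overlap_threshold Fraction above which a parcel counts as
#'   overlapping (0 = any nonzero overlap).
#' @return Tibble with `network_key` and `tissue_class`.
#' @export
stratify_by_tissue <- function(record, scheme, overlap_threshold = 0) {
  tf <- record$tumor_fraction[[1L]]
  ef <- record$edema_fraction[[1L]]
  p <- n_parcels(scheme)
  if (length(tf) != p || length(ef) != p) {
    abort("lesion fraction length does not match scheme",
          class = "connvae_format_error")
  }
  tibble(network_key = scheme$network_key, tf = tf, ef = ef) |>
    group_by(.data$network_key) |>
    summarise(tumor = any(.data$tf > overlap_threshold),
              edema = any(.data$ef > overlap_threshold), .groups = "drop") |>
    mutate(tissue_class = dplyr::case_when(
      tumor ~ "tumor", edema ~ "edema", TRUE ~ "healthy")) |>
    select("network_key", "tissue_class")
}

#' Per-subject network metrics from an anomaly result
#'
#' Computes NAD per network and modality, GD per modality, the two overlap
#' indices, and tissue classes of the altered networks.
#'
#' @param anomaly A `connvae_anomaly`.
#' @param record The subject's one-row cohort tibble.
#' @param scheme A `connvae_parcellation`.
#' @param overlap_threshold Passed to [stratify_by_tissue()].
#' @return A list of class `connvae_metrics`: `nad` (long tibble), `gd`
#'   (named numeric), `oi_fc`, `oi_sc`, `altered` (network keys per
#'   modality), `tissue` (network tissue classes), `subject_id`,
#'   `lesion_hemisphere`, `volume_T`, `volume_TO`.
#' @export
network_metrics <- function(anomaly, record, scheme, overlap_threshold = 0) {
  mods <- c("FC", "SC", "FCSC")
  nad_tabs <- lapply(mods, function(mod)
    mutate(nad(anomaly$impaired[[mod]], scheme), modality = mod))
  names(nad_tabs) <- mods
  altered <- lapply(nad_tabs, function(tb)
    tb$network_key[tb$n_impaired > 0L])
  gd_vals <- vapply(nad_tabs, gd, numeric(1))
  tissue <- stratify_by_tissue(record, scheme, overlap_threshold)
  structure(list(
    subject_id = record$subject_id[1L],
    nad = bind_rows(nad_tabs),
    gd = gd_vals,
    oi_fc = overlap_index(altered$FC, altered$FCSC),
    oi_sc = overlap_index(altered$SC, altered$FCSC),
    altered = altered,
    tissue = tissue,
    lesion_hemisphere = record$lesion_hemisphere[1L],
    volume_T = record$volume_T[1L],
    volume_TO = record$volume_TO[1L]
  ), class = "connvae_metrics")
}

#' One-row summary of a subject's network metrics
#' @param x A `connvae_metrics`.
#' @param ... Unused.
#' @return Tibble with GD per modality, OI values, lesion volumes.
#' @method glance connvae_metrics
#' @export
glance.connvae_metrics <- function(x, ...) {
  tibble(subject_id = x$subject_id,
         gd_fc = x$gd[["FC"]], gd_sc = x$gd[["SC"]],
         gd_fcsc = x$gd[["FCSC"]],
         oi_fc = x$oi_fc, oi_sc = x$oi_sc,
         lesion_hemisphere = x$lesion_hemisphere,
         volume_T = x$volume_T, volume_TO = x$volume_TO)
}

#' Long NAD table of a subject
#' @param x A `connvae_metrics`.
#' @param ... Unused.
#' @return Tibble of NAD values per network and modality with tissue class.
#' @method tidy connvae_metrics
#' @export
tidy.connvae_metrics <- function(x, ...) {
  left_join(x$nad, x$tissue, by = "network_key") |>
    mutate(subject_id = x$subject_id)
}

# exclusive modality combinations partitioning any altered network occurrence
combination_labels <- c("FC_only", "SC_only", "FCSC_only", "FC_and_FCSC",
                        "SC_and_FCSC", "FC_and_SC", "FC_and_SC_and_FCSC")

classify_combination <- function(in_fc, in_sc, in_fcsc) {
  dplyr::case_when(
    in_fc & in_sc & in_fcsc ~ "FC_and_SC_and_FCSC",
    in_fc & in_fcsc ~ "FC_and_FCSC",
    in_sc & in_fcsc ~ "SC_and_FCSC",
    in_fc & in_sc ~ "FC_and_SC",
    in_fc ~ "FC_only",
    in_sc ~ "SC_only",
    in_fcsc ~ "FCSC_only",
    TRUE ~ NA_character_
  )
}

#' Cohort-level alteration summary
#'
#' For every (network, tissue class, exclusive modality combination) cell,
#' the percentage of subjects showing that alteration; optionally grouped by
#' lesion hemisphere. Each altered network occurrence falls in exactly one
#' exclusive combination (FC only, SC only, FC+SC only, FC&FC+SC, SC&FC+SC,
#' FC&SC, FC&SC&FC+SC).
#'
#' @param metrics_list List of `connvae_metrics`.
#' @param by_hemisphere If `TRUE`, percentages are computed within
#'   lesion-hemisphere groups.
#' @return Tibble with `network_key`, `tissue_class`, `combination`,
#'   (`lesion_hemisphere`,) `n_subjects`, `n_altered`, `pct_subjects`.
#' @export
cohort_summary <- function(metrics_list, by_hemisphere = FALSE) {
  stopifnot(length(metrics_list) >= 1L)
  occ <- bind_rows(lapply(metrics_list, function(m) {
    keys <- unique(unlist(m$altered))
    if (!length(keys)) return(NULL)
    tibble(subject_id = m$subject_id,
           lesion_hemisphere = m$lesion_hemisphere,
           network_key = keys,
           in_fc = keys %in% m$altered$FC,
           in_sc = keys %in% m$altered$SC,
           in_fcsc = keys %in% m$altered$FCSC) |>
      left_join(m$tissue, by = "network_key")
  }))
  groups <- if (by_hemisphere) {
    split(seq_along(metrics_list),
          vapply(metrics_list, function(m) m$lesion_hemisphere, character(1)))
  } else list(all = seq_along(metrics_list))
  out <- list()
  for (g in names(groups)) {
    n_subj <- length(groups[[g]])
    ids <- vapply(metrics_list[groups[[g]]], function(m) m$subject_id,
                  character(1))
    sub <- occ[occ$subject_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) next
    # class occupancy of every network for the group's subjects, altered or
    # not (lesions move between subjects, so the per-class denominator does
    # too)
    class_n <- bind_rows(lapply(metrics_list[groups[[g]]],
                                function(m) m$tissue)) |>
      count(.data$network_key, .data$tissue_class, name = "n_in_class")
    tab <- sub |>
      mutate(combination = classify_combination(.data$in_fc, .data$in_sc,
                                                .data$in_fcsc)) |>
      group_by(.data$network_key, .data$tissue_class, .data$combination) |>
      summarise(n_altered = dplyr::n_distinct(.data$subject_id),
                .groups = "drop") |>
      left_join(class_n, by = c("network_key", "tissue_class")) |>
      mutate(lesion_hemisphere = g, n_subjects = n_subj,
             pct_subjects = 100 * .data$n_altered / n_subj,
             pct_within_class = 100 * .data$n_altered / .data$n_in_class)
    out[[g]] <- tab
  }
  res <- bind_rows(out)
  if (!by_hemisphere && nrow(res)) res$lesion_hemisphere <- NULL
  res
}

#' Tissue-conditional alteration frequencies
#'
#' For each lesion tissue class, the percentage of (subject, network)
#' occurrences of that class altered in each modality. Conditioning on class
#' membership matters because lesions move between subjects: a network is
#' tumor-class in only the few subjects whose lesion touches it, so
#' frequencies over all subjects would systematically deflate the lesioned
#' classes.
#'
#' @param metrics_list List of `connvae_metrics`.
#' @return Tibble with `tissue_class`, `modality`, `n_occurrences`,
#'   `pct_altered`.
#' @export
tissue_frequency <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L)
  occ <- bind_rows(lapply(metrics_list, function(m) {
    keys <- m$tissue$network_key
    tibble(subject_id = m$subject_id, network_key = keys,
           tissue_class = m$tissue$tissue_class,
           FC = keys %in% m$altered$FC,
           SC = keys %in% m$altered$SC,
           FCSC = keys %in% m$altered$FCSC)
  }))
  occ |>
    tidyr::pivot_longer(c("FC", "SC", "FCSC"), names_to = "modality",
                        values_to = "altered") |>
    group_by(.data$tissue_class, .data$modality) |>
    summarise(n_occurrences = dplyr::n(),
              pct_altered = 100 * mean(.data$altered), .groups = "drop")
}

#' Correlate network metrics with lesion volumes
#'
#' Runs the requested correlation (Pearson for GD-type metrics, Spearman for
#' OI-type) between each metric column and each volume column, excluding
#' undefined values pairwise, and adjusts the p-values of the whole family
#' with the Benjamini-Hochberg step-up procedure.
#'
#' @param data Tibble with one row per subject.
#' @param value_cols Names of the metric columns.
#' @param volume_cols Names of the volume columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble with `value`, `volume`, `method`, `n`, `estimate`,
#'   `p_value`, `p_adjusted` (`NA` estimates for degenerate input).
#' @export
associate_with_volume <- function(data, value_cols, volume_cols,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(value = value_cols, volume = volume_cols)
  rows <- purrr::pmap(grid, function(value, volume) {
    x <- data[[value]]; y <- data[[volume]]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) {
      abort("need at least 3 paired finite observations",
            class = "connvae_format_error")
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(value = value, volume = volume, method = method,
                    n = length(x), estimate = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    tibble(value = value, volume = volume, method = method, n = length(x),
           estimate = unname(ct$estimate), p_value = ct$p.value)
  })
  res <- bind_rows(rows)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}

#' Spider-style plot of cohort alteration frequencies
#'
#' @param summary_tbl Output of [cohort_summary()].
#' @param tissue Tissue class to display.
#' @return A ggplot bar chart of percentages per network and combination.
#' @export
plot_cohort_summary <- function(summary_tbl, tissue = "tumor") {
  df <- summary_tbl[summary_tbl$tissue_class == tissue, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_key,
                                   y = .data$pct_subjects,
                                   fill = .data$combination)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of subjects",
                  title = sprintf("Altered networks (%s tissue)", tissue)) +
    ggplot2::theme_minimal()
}
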