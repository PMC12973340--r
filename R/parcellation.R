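#' The 17 Yeo cortical network labels
#'
#' Standard abbreviations for the 17 Yeo resting-state networks used to label
#' Schaefer cortical parcels.
#'
#' @format Character vector of length 17.
#' @export
yeo17_networks <- c(
  "VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA", "DorsAttnB",
  "SalVentAttnA", "SalVentAttnB", "LimbicA", "LimbicB", "ControlA",
  "ControlB", "ControlC", "DefaultA", "DefaultB", "DefaultC", "TempPar"
)

# subcortical region labels that are merged into one "Subcortical" network
# per hemisphere
subcortical_labels <- c(
  "Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus", "Subcortical"
)

#' Build a validated parcellation scheme
#'
#' A parcellation scheme maps each parcel of the connectivity matrices to a
#' hemisphere and a functional network. Subcortical region labels are merged
#' into a single "Subcortical" network per hemisphere, so the default
#' 210-parcel scheme (200 Schaefer cortical parcels with Yeo-17 labels plus
#' 10 subcortical regions) yields 18 networks per hemisphere, 36 in total.
#' Parcel order is fixed and is the single source of truth for the row/column
#' order of every connectivity matrix in a run.
#'
#' @param parcels Data frame with columns `parcel_id`, `hemisphere`
#'   (`"left"`/`"right"`) and `network`. Row order defines parcel order.
#' @param merge_subcortical Character vector of network labels to merge into
#'   `"Subcortical"`.
#' @return A tibble of class `connvae_parcellation` with columns `parcel_id`,
#'   `hemisphere`, `network` and `network_key` (hemisphere-qualified network).
#' @export
parcellation <- function(parcels, merge_subcortical = subcortical_labels) {
  parcels <- as_tibble(parcels)
  req <- c("parcel_id", "hemisphere", "network")
  missing_cols <- setdiff(req, names(parcels))
  if (length(missing_cols)) {
    abort(paste("parcellation table lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "connvae_format_error")
  }
  if (nrow(parcels) == 0L) {
    abort("parcellation table is empty", class = "connvae_format_error")
  }
  parcels$parcel_id <- as.character(parcels$parcel_id)
  if (anyDuplicated(parcels$parcel_id)) {
    abort("duplicate parcel ids in parcellation table",
          class = "connvae_format_error")
  }
  bad_hemi <- setdiff(unique(parcels$hemisphere), c("left", "right"))
  if (length(bad_hemi)) {
    abort(paste("unknown hemisphere label:", paste(bad_hemi, collapse = ", ")),
          class = "connvae_format_error")
  }
  if (length(unique(parcels$hemisphere)) != 2L) {
    abort("parcellation must cover exactly 2 hemispheres",
          class = "connvae_format_error")
  }
  if (anyNA(parcels$network) || any(!nzchar(parcels$network))) {
    abort("every parcel must belong to exactly one network",
          class = "connvae_format_error")
  }
  parcels$network <- ifelse(parcels$network %in% merge_subcortical,
                            "Subcortical", parcels$network)
  parcels$network_key <- paste(parcels$hemisphere, parcels$network, sep = ":")
  out <- parcels[, c("parcel_id", "hemisphere", "network", "network_key")]
  class(out) <- c("connvae_parcellation", class(out))
  out
}

#' Default 210-parcel Schaefer + subcortical scheme
#'
#' 100 Schaefer cortical parcels per hemisphere distributed over the 17 Yeo
#' networks, plus 5 subcortical regions per hemisphere (thalamus, caudate,
#' putamen, pallidum, hippocampus) merged into one subcortical network, giving
#' 210 parcels and 36 hemisphere-specific networks.
#'
#' @return A `connvae_parcellation` with 210 parcels.
#' @export
schaefer_aal_parcellation <- function() {
  # distribute 100 parcels over the 17 Yeo networks: 15 networks of 6
  # parcels, 2 of 5
  sizes <- c(rep(6L, 15), rep(5L, 2))
  one_hemi <- function(h) {
    cort <- tibble(
      parcel_id = sprintf("%s_%s_%d", substr(h, 1, 1),
                          rep(yeo17_networks, sizes),
                          unlist(lapply(sizes, seq_len))),
      hemisphere = h,
      network = rep(yeo17_networks, sizes)
    )
    sub <- tibble(
      parcel_id = sprintf("%s_%s", substr(h, 1, 1),
                          c("Thalamus", "Caudate", "Putamen", "Pallidum",
                            "Hippocampus")),
      hemisphere = h,
      network = c("Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus")
    )
    bind_rows(cort, sub)
  }
  parcellation(bind_rows(one_hemi("left"), one_hemi("right")))
}

#' Compact synthetic parcellation for simulations
#'
#' Splits `n_parcels` evenly over two hemispheres and
#' `networks_per_hemisphere` networks per hemisphere. Used by the synthetic
#' cohort generator when working below the full 210-parcel scheme.
#'
#' @param n_parcels Even total parcel count.
#' @param networks_per_hemisphere Number of networks per hemisphere; must
#'   divide `n_parcels / 2`.
#' @return A `connvae_parcellation`.
#' @export
toy_parcellation <- function(n_parcels = 60, networks_per_hemisphere = 5) {
  if (n_parcels %% 2L != 0L) {
    abort("n_parcels must be even", class = "connvae_format_error")
  }
  per_hemi <- n_parcels %/% 2L
  if (per_hemi %% networks_per_hemisphere != 0L) {
    abort("networks_per_hemisphere must divide n_parcels/2",
          class = "connvae_format_error")
  }
  k <- per_hemi %/% networks_per_hemisphere
  one <- function(h) tibble(
    parcel_id = sprintf("%s%03d", substr(h, 1, 1), seq_len(per_hemi)),
    hemisphere = h,
    network = rep(sprintf("Net%02d", seq_len(networks_per_hemisphere)),
                  each = k)
  )
  parcellation(bind_rows(one("left"), one("right")))
}

#' Read a parcellation table from a tab-separated file
#'
#' @param path File with columns `parcel_id`, `hemisphere`, `network`.
#' @inheritParams parcellation
#' @return A `connvae_parcellation`.
#' @export
read_parcellation <- function(path, merge_subcortical = subcortical_labels) {
  if (!file.exists(path)) {
    abort(paste("parcellation file not found:", path),
          class = "connvae_io_error")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  parcellation(tab, merge_subcortical = merge_subcortical)
}

#' Write a parcellation table to a tab-separated file
#'
#' @param scheme A `connvae_parcellation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(scheme, path) {
  write.table(scheme[, c("parcel_id", "hemisphere", "network")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of parcels in a scheme
#' @param scheme A `connvae_parcellation`.
#' @return Integer parcel count.
#' @export
n_parcels <- function(scheme) nrow(scheme)

#' Network table of a parcellation scheme
#'
#' One row per hemisphere-specific network with its parcel count `K`.
#'
#' @param scheme A `connvae_parcellation`.
#' @return Tibble with `network_key`, `hemisphere`, `network`, `K`.
#' @export
networks <- function(scheme) {
  as_tibble(scheme) |>
    group_by(.data$network_key, .data$hemisphere, .data$network) |>
    summarise(K = dplyr::n(), .groups = "drop") |>
    arrange(.data$network_key)
}

#' @export
print.connvae_parcellation <- function(x, ...) {
  nets <- networks(x)
  cat(sprintf("<parcellation: %d parcels, %d networks (%s)>\n",
              nrow(x), nrow(nets),
              paste(table(nets$hemisphere), collapse = " + ")))
  NextMethod()
}
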