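connvae_splits <- c("train", "validation", "test",
                    "finetune_train", "finetune_val")

#' Construct subject records for a cohort
#'
#' One row per subject with cohort membership, data split, matrix file paths
#' and lesion information. Healthy subjects are auto-filled with zero lesion
#' fractions and `lesion_hemisphere = "none"`. Lesion overlap is consumed as
#' per-parcel fractions (tumor core T and edema O); per parcel the two
#' fractions may not sum above 1.
#'
#' @param records Data frame / tibble with columns `subject_id`, `cohort`
#'   (`"healthy"`/`"glioma"`), `split`, `fc_path`, `sc_path`, and for glioma
#'   subjects list-columns `tumor_fraction`, `edema_fraction` (numeric length
#'   P), `volume_T`, `volume_TO`, `lesion_hemisphere`. An optional
#'   `excluded_parcels` list-column of parcel ids is carried through but
#'   unused by default.
#' @param scheme Optional parcellation; lesion fraction vectors must have one
#'   entry per parcel.
#' @return A tibble of class `connvae_cohort`.
#' @export
subject_records <- function(records, scheme = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    abort("empty cohort", class = "connvae_format_error")
  }
  req <- c("subject_id", "cohort", "split")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste("cohort manifest lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "connvae_format_error")
  }
  if (anyDuplicated(records$subject_id)) {
    abort("duplicate subject ids", class = "connvae_format_error")
  }
  bad <- setdiff(unique(records$cohort), c("healthy", "glioma"))
  if (length(bad)) {
    abort(paste("unknown cohort:", paste(bad, collapse = ", ")),
          class = "connvae_format_error")
  }
  bad <- setdiff(unique(records$split), connvae_splits)
  if (length(bad)) {
    abort(paste("unknown split:", paste(bad, collapse = ", ")),
          class = "connvae_format_error")
  }
  p <- if (!is.null(scheme)) n_parcels(scheme) else NULL
  if (!"lesion_hemisphere" %in% names(records)) {
    records$lesion_hemisphere <- NA_character_
  }
  if (!"volume_T" %in% names(records)) records$volume_T <- NA_real_
  if (!"volume_TO" %in% names(records)) records$volume_TO <- NA_real_
  if (!"tumor_fraction" %in% names(records)) {
    records$tumor_fraction <- vector("list", nrow(records))
  }
  if (!"edema_fraction" %in% names(records)) {
    records$edema_fraction <- vector("list", nrow(records))
  }
  if (!"excluded_parcels" %in% names(records)) {
    records$excluded_parcels <- vector("list", nrow(records))
  }
  for (i in seq_len(nrow(records))) {
    if (records$cohort[i] == "healthy") {
      np <- p %||% length(records$tumor_fraction[[i]]) %||% 0L
      tf <- records$tumor_fraction[[i]]
      ef <- records$edema_fraction[[i]]
      if ((!is.null(tf) && any(tf > 0)) || (!is.null(ef) && any(ef > 0))) {
        abort(sprintf("healthy subject %s has nonzero lesion fractions",
                      records$subject_id[i]), class = "connvae_format_error")
      }
      records$tumor_fraction[[i]] <- rep(0, max(np, 1L) * (np > 0))
      records$edema_fraction[[i]] <- rep(0, max(np, 1L) * (np > 0))
      records$lesion_hemisphere[i] <- "none"
      records$volume_T[i] <- 0
      records$volume_TO[i] <- 0
    } else {
      tf <- records$tumor_fraction[[i]]
      ef <- records$edema_fraction[[i]]
      if (is.null(tf) || is.null(ef)) {
        abort(sprintf("glioma subject %s lacks lesion fractions",
                      records$subject_id[i]), class = "connvae_format_error")
      }
      if (!is.null(p) && (length(tf) != p || length(ef) != p)) {
        abort(sprintf("subject %s lesion fractions have wrong length",
                      records$subject_id[i]), class = "connvae_format_error")
      }
      if (any(tf < 0 | tf > 1) || any(ef < 0 | ef > 1)) {
        abort(sprintf("subject %s lesion fractions outside [0,1]",
                      records$subject_id[i]), class = "connvae_format_error")
      }
      if (any(tf + ef > 1 + 1e-12)) {
        abort(sprintf(
          "subject %s: tumor_fraction + edema_fraction > 1 at some parcel",
          records$subject_id[i]), class = "connvae_format_error")
      }
      if (!records$lesion_hemisphere[i] %in%
            c("left", "right", "bilateral", "none")) {
        abort(sprintf("subject %s has invalid lesion_hemisphere",
                      records$subject_id[i]), class = "connvae_format_error")
      }
    }
  }
  class(records) <- c("connvae_cohort", class(records))
  records
}

#' Write a cohort manifest as JSON
#'
#' @param records A `connvae_cohort` tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(records, path) {
  lst <- lapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, setdiff(names(records),
                                    c("tumor_fraction", "edema_fraction",
                                      "excluded_parcels"))])
    r <- lapply(r, function(v) if (is.list(v)) v[[1L]] else v)
    r$tumor_fraction <- records$tumor_fraction[[i]]
    r$edema_fraction <- records$edema_fraction[[i]]
    r$excluded_parcels <- records$excluded_parcels[[i]]
    r
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a cohort manifest written by [write_cohort_manifest()]
#'
#' @param path Manifest JSON path.
#' @param scheme Optional parcellation used to validate lesion vectors.
#' @param check_files If `TRUE`, every referenced matrix file must exist
#'   (paths are resolved relative to the manifest's directory when not
#'   absolute).
#' @return A `connvae_cohort` tibble.
#' @export
read_cohort_manifest <- function(path, scheme = NULL, check_files = TRUE) {
  if (!file.exists(path)) {
    abort(paste("manifest not found:", path), class = "connvae_io_error")
  }
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(lst) == 0L) abort("empty cohort", class = "connvae_format_error")
  base <- dirname(path)
  resolve <- function(pp) {
    if (is.null(pp) || is.na(pp)) return(NA_character_)
    if (file.exists(pp) || grepl("^/", pp)) pp else file.path(base, pp)
  }
  rows <- lapply(lst, function(r) {
    tibble(
      subject_id = r$subject_id, cohort = r$cohort, split = r$split,
      fc_path = resolve(r$fc_path %||% NA_character_),
      sc_path = resolve(r$sc_path %||% NA_character_),
      lesion_hemisphere = r$lesion_hemisphere %||% NA_character_,
      volume_T = as.numeric(r$volume_T %||% NA_real_),
      volume_TO = as.numeric(r$volume_TO %||% NA_real_),
      tumor_fraction = list(as.numeric(unlist(r$tumor_fraction))),
      edema_fraction = list(as.numeric(unlist(r$edema_fraction))),
      excluded_parcels = list(as.character(unlist(r$excluded_parcels)))
    )
  })
  records <- subject_records(bind_rows(rows), scheme = scheme)
  if (check_files) {
    for (col in c("fc_path", "sc_path")) {
      pp <- records[[col]]
      bad <- !is.na(pp) & !file.exists(pp)
      if (any(bad)) {
        abort(paste("missing matrix file(s):",
                    paste(head(pp[bad], 3), collapse = ", ")),
              class = "connvae_io_error")
      }
    }
  }
  records
}
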