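connvae_modalities <- c("FC", "SC", "SC_counts", "zFC", "zSC",
                        "FC_recon", "SC_recon",
                        "diff_FC", "diff_SC", "diff_FCSC")

#' Construct a validated connectivity matrix
#'
#' Checks the matrix contract shared by every stage of the pipeline: square,
#' symmetric within `tol` (small asymmetries are averaged away, larger ones
#' rejected as data errors), zero diagonal, FC values in \[-1, 1\], SC values
#' non-negative. `NA` entries are permitted as the missing-parcel sentinel.
#'
#' @param values Square numeric matrix.
#' @param modality One of `"FC"`, `"SC"`, `"SC_counts"`, `"zFC"`, `"zSC"`,
#'   `"FC_recon"`, `"SC_recon"`, `"diff_FC"`, `"diff_SC"`, `"diff_FCSC"`.
#' @param subject_id Optional subject identifier.
#' @param scheme Optional `connvae_parcellation`; when given, the matrix
#'   dimension must equal the parcel count.
#' @param tol Symmetrization tolerance.
#' @return The validated matrix with attributes `modality` and `subject_id`,
#'   class `conn_matrix`.
#' @export
conn_matrix <- function(values, modality, subject_id = NA_character_,
                        scheme = NULL, tol = 1e-9) {
  modality <- match.arg(modality, connvae_modalities)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("connectivity values must be a numeric matrix",
          class = "connvae_format_error")
  }
  if (!is.null(scheme) && !all(dim(values) == n_parcels(scheme))) {
    abort(sprintf("matrix is %dx%d but scheme has %d parcels",
                  nrow(values), ncol(values), n_parcels(scheme)),
          class = "connvae_format_error")
  }
  has_na <- anyNA(values)
  if (has_na) {
    # sentinel rows/cols (excluded parcels): validate the finite part only
    filled <- values
    filled[is.na(filled)] <- 0
    filled <- check_symmetric(filled, tol, paste(modality, "matrix"))
    na_mask <- is.na(values) | is.na(t(values))
    values <- filled
    values[na_mask] <- NA_real_
    diag(values) <- 0
  } else {
    if (any(!is.finite(values))) {
      abort("non-finite connectivity values", class = "connvae_format_error")
    }
    values <- check_symmetric(values, tol, paste(modality, "matrix"))
  }
  fin <- values[!is.na(values)]
  if (modality %in% c("FC", "FC_recon") && any(fin < -1 | fin > 1)) {
    abort("FC values outside [-1, 1]", class = "connvae_format_error")
  }
  if (modality %in% c("SC", "SC_counts", "SC_recon") && any(fin < 0)) {
    abort("negative SC values", class = "connvae_format_error")
  }
  structure(values, modality = modality, subject_id = subject_id,
            class = c("conn_matrix", class(values)))
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix %s subject=%s %dx%d>\n",
              attr(x, "modality"), attr(x, "subject_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write a connectivity matrix to a delimited text file
#'
#' Tab-separated values preceded by a one-line header comment carrying the
#' subject id and modality. Values are written with 17 significant digits so
#' a write/read round trip is bit-exact for finite doubles.
#'
#' @param m Matrix (ideally from [conn_matrix()]).
#' @param path Output path.
#' @param modality,subject_id Overrides for the header; default to the
#'   matrix attributes.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(m, path, modality = attr(m, "modality"),
                              subject_id = attr(m, "subject_id")) {
  header <- sprintf("# subject=%s modality=%s",
                    subject_id %||% NA_character_, modality %||% NA_character_)
  body <- apply(unclass(m), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a connectivity matrix written by [write_conn_matrix()]
#'
#' @param path File path.
#' @param modality Expected modality; validated against the file header when
#'   the header carries one.
#' @param scheme Optional parcellation for dimension validation.
#' @param tol Symmetrization tolerance.
#' @return A validated `conn_matrix`.
#' @export
read_conn_matrix <- function(path, modality, scheme = NULL, tol = 1e-9) {
  if (!file.exists(path)) {
    abort(paste("matrix file not found:", path), class = "connvae_io_error")
  }
  lines <- readLines(path)
  subject_id <- NA_character_
  if (length(lines) && startsWith(lines[1L], "#")) {
    h <- lines[1L]
    sm <- regmatches(h, regexec("subject=(\\S+)", h))[[1L]]
    if (length(sm) == 2L) subject_id <- sm[2L]
    mm <- regmatches(h, regexec("modality=(\\S+)", h))[[1L]]
    if (length(mm) == 2L && !missing(modality) && mm[2L] != modality) {
      abort(sprintf("file declares modality %s, expected %s", mm[2L], modality),
            class = "connvae_format_error")
    }
    if (missing(modality) && length(mm) == 2L) modality <- mm[2L]
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "[\t ,]+"), as.numeric)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L || length(rows) != ncols[1L]) {
    abort(sprintf("matrix file is %d x %s, not square",
                  length(rows), paste(unique(ncols), collapse = "/")),
          class = "connvae_format_error")
  }
  values <- do.call(rbind, rows)
  conn_matrix(values, modality = modality, subject_id = subject_id,
              scheme = scheme, tol = tol)
}
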