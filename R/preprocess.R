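#' Functional connectivity from parcel time series
#'
#' Pearson correlation between the mean time series of every pair of parcels,
#' with zero diagonal. Parcels flagged in `exclude` (e.g. overlapping necrotic
#' tissue, whose voxels are discarded upstream) get sentinel (`NA`) rows and
#' columns. Constant series have undefined correlations and are likewise
#' turned into sentinels, with a warning.
#'
#' @param series Numeric matrix or data frame, time points in rows, parcels
#'   in columns (at least 3 time points).
#' @param exclude Optional logical vector, one flag per parcel.
#' @param subject_id Optional id attached to the result.
#' @return A `conn_matrix` of modality `"FC"` with `NA` sentinel rows for
#'   excluded/degenerate parcels.
#' @export
fc_from_timeseries <- function(series, exclude = NULL,
                               subject_id = NA_character_) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) {
    abort("need at least 3 time points", class = "connvae_format_error")
  }
  p <- ncol(series)
  if (is.null(exclude)) exclude <- rep(FALSE, p)
  if (length(exclude) != p) {
    abort("exclude flag length must match parcel count",
          class = "connvae_format_error")
  }
  sds <- apply(series, 2L, sd)
  degenerate <- !exclude & (is.na(sds) | sds == 0)
  if (any(degenerate)) {
    warn(sprintf("%d constant time series; correlations set to sentinel",
                 sum(degenerate)))
  }
  drop <- exclude | degenerate
  fc <- suppressWarnings(cor(series, method = "pearson"))
  fc[drop, ] <- NA_real_
  fc[, drop] <- NA_real_
  diag(fc) <- 0
  # guard against |r| marginally above 1 from floating point
  fc[!is.na(fc)] <- pmin(1, pmax(-1, fc[!is.na(fc)]))
  conn_matrix(fc, "FC", subject_id = subject_id)
}

#' Normalize streamline counts into connection fractions
#'
#' Divides each entry of a streamline-count matrix by the total number of
#' tracts in the tractogram (10 million by default). Entries counting exactly
#' one streamline are set to zero first, treating singleton streamlines as
#' tractography noise.
#'
#' @param counts Symmetric non-negative integer matrix of streamline counts.
#' @param total_streamlines Total tract count of the tractogram.
#' @param subject_id Optional id attached to the result.
#' @return A `conn_matrix` of modality `"SC"` with entries in `[0, 1]`.
#' @export
normalize_sc_counts <- function(counts, total_streamlines = 1e7,
                                subject_id = NA_character_) {
  counts <- unclass(counts)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("negative streamline count", class = "connvae_format_error")
  }
  counts <- check_symmetric(counts, tol = 1e-9, what = "SC count matrix")
  out <- counts / total_streamlines
  out[counts == 1] <- 0
  conn_matrix(out, "SC", subject_id = subject_id)
}

#' Normalization parameters for the SC power-law transform
#'
#' @param alpha Power-law exponent (> 0).
#' @param sc_max Reference maximum SC weight, frozen from the healthy
#'   training split.
#' @param epsilon_clip Clipping margin keeping transformed values inside the
#'   open artanh domain.
#' @return A list of class `connvae_norm_params`.
#' @export
norm_params <- function(alpha, sc_max, epsilon_clip = 1e-6) {
  stopifnot(alpha > 0, sc_max > 0, epsilon_clip > 0, epsilon_clip < 1e-2)
  structure(list(alpha = alpha, sc_max = sc_max,
                 sc_scale = 1 - epsilon_clip, epsilon_clip = epsilon_clip),
            class = "connvae_norm_params")
}

# two-sample Kolmogorov-Smirnov sup-distance on ecdfs
ks_distance <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

#' Fit the power-law exponent harmonizing SC with FC
#'
#' Finds the exponent `alpha` on a fixed grid (0.01 to 1.00, step 0.01) that
#' minimizes the Kolmogorov-Smirnov distance between the distribution of
#' `(sc / max(sc))^alpha * sc_scale` and the distribution of `|fc|`. This
#' data-driven power-law transform reshapes the heavy-tailed streamline-
#' fraction distribution to resemble the FC weight distribution so both
#' modalities can share one normalization. Fitted once on the pooled healthy
#' training split and frozen for all other subjects.
#'
#' @param sc_weights Strictly positive sample of nonzero SC weights.
#' @param fc_weights Sample of FC weights.
#' @param epsilon_clip Clipping margin (transformed SC maximum becomes
#'   `1 - epsilon_clip`).
#' @param grid Candidate exponents.
#' @return A `connvae_norm_params`.
#' @export
fit_civier_exponent <- function(sc_weights, fc_weights, epsilon_clip = 1e-6,
                                grid = seq(0.01, 1, by = 0.01)) {
  sc_weights <- sc_weights[is.finite(sc_weights)]
  fc_weights <- fc_weights[is.finite(fc_weights)]
  if (!length(sc_weights) || !length(fc_weights)) {
    abort("empty weight sample", class = "connvae_format_error")
  }
  if (any(sc_weights <= 0)) {
    abort("SC weight sample must be strictly positive",
          class = "connvae_format_error")
  }
  sc_max <- max(sc_weights)
  if (diff(range(sc_weights)) == 0) {
    warn("all SC weights identical; alpha fixed at 1")
    return(norm_params(1, sc_max, epsilon_clip))
  }
  target <- abs(fc_weights)
  base <- sc_weights / sc_max
  d <- vapply(grid, function(a)
    ks_distance(base^a * (1 - epsilon_clip), target), numeric(1))
  norm_params(grid[which.min(d)], sc_max, epsilon_clip)
}

#' Apply the fitted power-law transform to an SC matrix
#'
#' Zero entries stay zero; nonzero entries map to
#' `(sc / sc_max)^alpha * sc_scale`, capped at `1 - epsilon_clip` for weights
#' above the frozen training maximum. Monotone in the input.
#'
#' @param sc SC matrix (normalized streamline fractions).
#' @param params A `connvae_norm_params` from [fit_civier_exponent()].
#' @return A `conn_matrix` of modality `"zSC"`-ready transformed SC (entries
#'   in `[0, 1 - epsilon_clip]`), tagged `"SC"` domain `transformed`.
#' @export
apply_power_transform <- function(sc, params) {
  stopifnot(inherits(params, "connvae_norm_params"))
  sid <- attr(sc, "subject_id") %||% NA_character_
  m <- unclass(sc)
  nz <- !is.na(m) & m != 0
  out <- m
  out[nz] <- pmin((m[nz] / params$sc_max)^params$alpha, 1) * params$sc_scale
  res <- conn_matrix(out, "SC", subject_id = sid)
  attr(res, "domain") <- "transformed"
  res
}

#' Inverse hyperbolic tangent normalization and its inverse
#'
#' Elementwise `atanh` mapping `[-1, 1]`-bounded connectivity into the reals
#' (the Fisher z transform for FC). Entries with magnitude above
#' `1 - epsilon_clip` are clipped to the open domain first. `tanh_denormalize`
#' inverts the map.
#'
#' @param m Numeric matrix (or vector) with entries in `[-1, 1]`.
#' @param epsilon_clip Clipping margin.
#' @return Matrix of the same shape.
#' @export
artanh_normalize <- function(m, epsilon_clip = 1e-6) {
  v <- unclass(m)
  if (any(!is.finite(v) & !is.na(v))) {
    abort("non-finite input to artanh_normalize",
          class = "connvae_format_error")
  }
  lim <- 1 - epsilon_clip
  v <- pmin(pmax(v, -lim), lim)  # matrix first: pmin/pmax keep its dim
  atanh(v)
}

#' @rdname artanh_normalize
#' @export
tanh_denormalize <- function(m, epsilon_clip = 1e-6) {
  tanh(unclass(m))
}

#' Upper-triangle vectorization
#'
#' Extracts the strict upper triangle in fixed row-major order over pairs
#' `i < j` (row 1 against columns 2..P, then row 2 against 3..P, ...). This
#' ordering is the package-wide convention for model vectors.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `P(P-1)/2`.
#' @export
vectorize_upper <- function(m) {
  m <- unclass(m)
  if (!is_square(m)) abort("matrix must be square", class = "connvae_format_error")
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' @rdname vectorize_upper
#' @param v Vector of length `P(P-1)/2`.
#' @param p Parcel count.
#' @return `devectorize_upper`: symmetric `P x P` matrix with zero diagonal.
#' @export
devectorize_upper <- function(v, p) {
  if (length(v) != p * (p - 1) / 2) {
    abort(sprintf("vector length %d does not match P = %d (need %d)",
                  length(v), p, p * (p - 1) / 2),
          class = "connvae_format_error")
  }
  tm <- matrix(0, p, p)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m + t(m)
}

#' Concatenate normalized FC and transformed-SC blocks into a model vector
#'
#' zFC upper triangle first, then zSC upper triangle; length
#' `2 * P(P-1)/2`. Sentinel (`NA`) entries are replaced by 0 so the model
#' input stays finite.
#'
#' @param zfc,zsc_transformed Same-dimension square matrices (artanh domain).
#' @param subject_id Optional id attached as an attribute.
#' @return Numeric vector of length `P(P-1)`.
#' @export
build_model_vector <- function(zfc, zsc_transformed,
                               subject_id = NA_character_) {
  if (!all(dim(unclass(zfc)) == dim(unclass(zsc_transformed)))) {
    abort("zFC and zSC dimensions differ", class = "connvae_format_error")
  }
  v <- c(vectorize_upper(zfc), vectorize_upper(zsc_transformed))
  v[is.na(v)] <- 0
  attr(v, "subject_id") <- subject_id
  v
}

#' Preprocess one subject's FC and SC-count matrices into model inputs
#'
#' Runs the full normalization chain: SC counts are divided by the total
#' streamline count (singletons zeroed), power-transformed with the frozen
#' parameters, then both modalities are artanh-normalized and concatenated.
#'
#' @param fc FC `conn_matrix`.
#' @param sc_counts SC streamline-count matrix.
#' @param params Frozen `connvae_norm_params`.
#' @param total_streamlines Tractogram size.
#' @return List with `fc`, `sc_transformed` (Civier domain), `zfc`, `zsc`,
#'   and `model_vector`.
#' @export
preprocess_subject <- function(fc, sc_counts, params,
                               total_streamlines = 1e7) {
  sid <- attr(fc, "subject_id") %||% NA_character_
  sc <- normalize_sc_counts(sc_counts, total_streamlines, subject_id = sid)
  sct <- apply_power_transform(sc, params)
  zfc <- artanh_normalize(fc, params$epsilon_clip)
  zsc <- artanh_normalize(sct, params$epsilon_clip)
  list(fc = fc, sc_transformed = sct, zfc = zfc, zsc = zsc,
       model_vector = build_model_vector(zfc, zsc, subject_id = sid))
}
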