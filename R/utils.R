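#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n count across rename
#' @importFrom purrr map map_dbl map_chr map_lgl map_int imap pmap
#' @importFrom stats quantile cor cor.test sd rnorm runif rlnorm p.adjust
#'   setNames
#' @importFrom utils head read.delim write.table
NULL

# Deterministic sub-seed derivation so each pipeline stage / subject draws
# from an independent, reproducible stream. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# symmetrize if asymmetry is within tol, otherwise signal a data error
check_symmetric <- function(m, tol = 1e-9, what = "matrix") {
  if (!is_square(m)) abort(sprintf("%s must be square", what), class = "connvae_format_error")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    abort(sprintf("%s asymmetry %.3g exceeds tolerance %.1g", what, asym, tol),
          class = "connvae_format_error")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
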