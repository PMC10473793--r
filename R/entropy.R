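#' Multiscale entropy parameters
#'
#' Bundles the sample-entropy pattern length `m`, the tolerance fraction `r`
#' (expressed as a fraction of the time-series standard deviation), and the
#' number of temporal scales used for coarse-graining.  The defaults (m = 2,
#' r = 0.3, 15 scales) are the values commonly used for BOLD time series of a
#' few hundred volumes.
#'
#' @param m Pattern (template) length, an integer >= 1.
#' @param r Tolerance as a fraction of the series SD, > 0.
#' @param scales Number of temporal scales, an integer >= 1.
#' @param tolerance_reference Either `"original_scale_sd"` (the Costa
#'   convention: the absolute tolerance is fixed at `r` times the SD of the
#'   unsmoothed, scale-1 series and reused at every scale) or
#'   `"per_scale_sd"` (the tolerance is recomputed from each coarse-grained
#'   series).
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.3, scales = 15L,
                           tolerance_reference = c("original_scale_sd",
                                                   "per_scale_sd")) {
  m <- as.integer(m); scales <- as.integer(scales)
  if (is.na(m) || m < 1L) stop("pattern length 'm' must be >= 1")
  if (!is.finite(r) || r <= 0) stop("tolerance fraction 'r' must be > 0")
  if (is.na(scales) || scales < 1L) stop("'scales' must be >= 1")
  structure(list(m = m, r = r, scales = scales,
                 tolerance_reference = match.arg(tolerance_reference)),
            class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat(sprintf("entropy_params: m = %d, r = %g x SD, scales = %d (%s)\n",
              x$m, x$r, x$scales, x$tolerance_reference))
  invisible(x)
}

# population (divide-by-N) standard deviation; used for the tolerance so that
# r_abs is a deterministic function of the data, independent of Bessel's
# correction
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Coarse-grain a time series
#'
#' Non-overlapping block averaging: element k of the output is the mean of
#' input elements `(k-1)*scale + 1 ... k*scale`.  Trailing points that do not
#' fill a complete block are dropped, so the output has `floor(N/scale)`
#' points.  The effective sampling interval grows by the scale factor.
#'
#' @param x Numeric vector (one BOLD time series).
#' @param scale Integer scale factor >= 1 and <= `length(x)`.
#' @return Numeric vector of length `floor(length(x)/scale)`.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  n <- length(x)
  if (is.na(scale) || scale < 1L) stop("'scale' must be >= 1")
  if (scale > n) stop("'scale' exceeds series length")
  if (scale == 1L) return(x)
  nb <- n %/% scale
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Sample entropy of a time series
#'
#' SampEn(m, r) is the negative natural logarithm of the conditional
#' probability that two sequences matching for m points (Chebyshev distance
#' at most `r_abs`, self-matches excluded) also match for m + 1 points.
#' Template start indices for both the m- and (m+1)-point pools run over
#' `1 .. N - m`, which guarantees SampEn = 0 for a constant series.  When no
#' template pair matches at length m (or none extends to m + 1) the
#' conditional probability is undefined and `NA` is returned rather than a
#' substitute ceiling value.
#'
#' @param x Numeric vector, finite values, length >= m + 2.
#' @param m Pattern length.
#' @param r_abs Absolute tolerance, in the units of `x` (>= 0).  Note this is
#'   an absolute tolerance; [multiscale_entropy()] derives it from the
#'   relative fraction in [entropy_params()].
#' @return SampEn in nats, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  m <- as.integer(m)
  if (anyNA(x) || !all(is.finite(x))) stop("series contains non-finite values")
  if (length(x) < m + 2L) stop("series too short: need length >= m + 2")
  if (!is.finite(r_abs) || r_abs < 0) stop("'r_abs' must be >= 0")
  cnt <- .sampen_counts(as.numeric(x), m, r_abs)
  if (cnt[["A"]] == 0 || cnt[["B"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Multiscale entropy profile
#'
#' Computes SampEn of the coarse-grained series at scales `1 .. scales` and
#' summarizes them as MSE, the arithmetic mean of the finite per-scale
#' values.  Under the default tolerance convention the absolute tolerance is
#' `r` times the population SD of the original series, held fixed across
#' scales.
#'
#' @param x Numeric vector (one BOLD time series).
#' @param params An [entropy_params()] object.
#' @return An object of class `entropy_profile`: list with `sampen` (per-scale
#'   values, `NA` where undefined), `mse`, `n_valid_scales`, `scales`,
#'   `params`.
#' @export
multiscale_entropy <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  n <- length(x)
  if (n < params$scales * (params$m + 2L))
    warning(sprintf("series length %d < scales * (m + 2) = %d; high scales may be unreliable",
                    n, params$scales * (params$m + 2L)))
  if (anyNA(x) || !all(is.finite(x))) stop("series contains non-finite values")
  r_ref <- params$r * pop_sd(x)
  se <- .mse_profile(as.numeric(x), params$m, params$scales, r_ref, params$r,
                     if (params$tolerance_reference == "per_scale_sd") 1L
                     else 0L)
  valid <- sum(!is.na(se))
  if (valid == 0L) stop("sample entropy undefined at every scale")
  structure(list(sampen = se, mse = mean(se, na.rm = TRUE),
                 n_valid_scales = valid, scales = seq_len(params$scales),
                 params = params),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile: MSE = %.4f over %d/%d valid scales\n",
              x$mse, x$n_valid_scales, length(x$sampen)))
  invisible(x)
}

#' Sampling frequency of a coarse-grained series
#'
#' At scale s the coarse-grained series has sampling interval `s * tr`, so
#' its sampling frequency is `1 / (s * tr)` Hz; for TR = 0.8 s this gives
#' 1.25 Hz at scale 1 and 0.083 Hz at scale 15.
#'
#' @param scale Integer scale >= 1.
#' @param tr Repetition time in seconds, > 0.
#' @return Frequency in Hz.
#' @export
scale_to_frequency <- function(scale, tr = 0.8) {
  if (any(scale < 1)) stop("'scale' must be >= 1")
  if (any(tr <= 0)) stop("'tr' must be > 0")
  1 / (scale * tr)
}
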