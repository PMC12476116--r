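#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' For each time course, the discrete Fourier spectrum is computed and
#' fALFF is the spectral mass in a low-frequency band (default
#' 0.01-0.1 Hz) divided by the mass over all positive frequencies up to
#' Nyquist. The DC bin is excluded from both sums, so the raw value lies
#' in \[0, 1\] and is invariant to positive rescaling of the series.
#'
#' `spectrum = "amplitude"` (default) sums Fourier amplitudes, i.e. the
#' square root of power, following the usual low-frequency-fluctuation
#' convention; `"power"` sums squared amplitudes. A linear trend is
#' removed before the transform by default to keep trend energy from
#' leaking into the band; pass `detrend = FALSE` for analytically exact
#' single-bin checks.
#'
#' @param series numeric vector (one time course) or matrix with time in
#'   rows and voxels in columns.
#' @param tr repetition time in seconds (sampling interval).
#' @param band numeric length-2, band edges in Hz.
#' @param spectrum `"amplitude"` or `"power"`.
#' @param detrend remove a linear trend before the transform?
#' @return numeric vector of raw fALFF values, one per column, with
#'   attribute `flagged` marking constant (zero-spectrum) series, which
#'   are defined as 0.
#' @export
compute_falff <- function(series, tr, band = c(0.01, 0.1),
                          spectrum = c("amplitude", "power"),
                          detrend = TRUE) {
  spectrum <- match.arg(spectrum)
  x <- as.matrix(series)
  .assert(all(is.finite(x)), "series must be finite")
  .assert(tr > 0, "tr must be positive", "tr")
  .assert(length(band) == 2 && band[1] > 0 && band[2] > band[1],
          "band must be increasing and positive", "band")
  n <- nrow(x)
  .assert(n >= 4, "need at least 4 timepoints")
  f0 <- 1 / (n * tr)
  if (f0 > band[1] + 1e-12)
    warning(sprintf("band lower edge %.4g Hz unresolvable: fundamental frequency is %.4g Hz",
                    band[1], f0))
  if (detrend) {
    tt <- seq_len(n) - (n + 1) / 2
    slope <- crossprod(tt, x) / sum(tt^2)
    x <- sweep(x, 2, colMeans(x), "-") - outer(tt, drop(slope))
  }
  sp <- mvfft(x)
  k <- seq_len(floor(n / 2))            # positive-frequency bins, DC excluded
  freq <- k / (n * tr)
  amp <- abs(sp[k + 1, , drop = FALSE])
  if (spectrum == "power") amp <- amp^2
  inband <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  tot <- colSums(amp)
  num <- colSums(amp[inband, , drop = FALSE])
  flagged <- tot <= .Machine$double.eps * n
  out <- ifelse(flagged, 0, num / pmax(tot, .Machine$double.eps))
  if (any(flagged)) warning("constant series encountered; fALFF defined as 0")
  attr(out, "flagged") <- flagged
  out
}

#' Standardize a map by its in-mask global mean
#'
#' Divides every in-mask value by the mean over the mask, so the
#' standardized map has in-mask mean 1 and is invariant to rescaling of
#' the input. Out-of-mask values are set to 0.
#'
#' @param raw numeric vector or array of raw values.
#' @param mask logical vector/array of the same length; `NULL` means all.
#' @return standardized map, same shape as `raw`.
#' @export
standardize_global_mean <- function(raw, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(raw))
  .assert(length(mask) == length(raw), "mask and map sizes differ", "mask")
  m <- mean(raw[mask])
  .assert(is.finite(m) && m != 0, "in-mask mean is zero; cannot standardize")
  out <- raw
  out[mask] <- raw[mask] / m
  out[!mask] <- 0
  out
}
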