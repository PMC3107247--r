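#' Wavelet analysis specification
#'
#' Bundles the complex-Morlet parameters used throughout the pipeline: the
#' mother wavelet's center frequency, the Gaussian envelope bandwidth, and the
#' set of analysis (pseudo-)frequencies at which scalograms are computed.
#'
#' The mother wavelet is
#' \deqn{\psi(u) = (\pi f_b)^{-1/2} \exp(2\pi i f_c u) \exp(-u^2 / f_b),}
#' a Gaussian-modulated complex sinusoid. Its envelope standard deviation is
#' \eqn{\sqrt{f_b/2}}, so the default `bandwidth = 2` gives a mother envelope
#' whose central \eqn{\pm 1} SD window spans 2 s and, at every scale, covers
#' two full cycles of the carrier — the narrowest envelope that still holds
#' two cycles, favouring temporal over spectral precision.
#'
#' @param center_frequency Center frequency \eqn{f_c} of the mother wavelet
#'   (Hz). Default 1.
#' @param bandwidth Envelope bandwidth parameter \eqn{f_b} of the mother
#'   wavelet (squared mother-time units). Default 2.
#' @param frequencies Analysis frequencies in Hz, strictly positive and
#'   strictly increasing. Default 5 to 30 Hz in steps of 5.
#' @return An object of class `wavelet_spec`.
#' @examples
#' wavelet_spec()
#' @export
wavelet_spec <- function(center_frequency = 1, bandwidth = 2,
                         frequencies = seq(5, 30, by = 5)) {
  stop_if_not_scalar_pos(center_frequency, "center_frequency")
  stop_if_not_scalar_pos(bandwidth, "bandwidth")
  if (!is.numeric(frequencies) || length(frequencies) < 1L ||
      any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("`frequencies` must be positive finite numbers", call. = FALSE)
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("`frequencies` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(center_frequency = center_frequency,
         bandwidth = bandwidth,
         frequencies = as.numeric(frequencies)),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("Complex Morlet wavelet spec\n")
  cat(sprintf("  center frequency: %g Hz\n", x$center_frequency))
  cat(sprintf("  envelope bandwidth fb: %g\n", x$bandwidth))
  cat(sprintf("  analysis frequencies: %s Hz\n",
              paste(x$frequencies, collapse = ", ")))
  invisible(x)
}

#' Pseudo-frequency of a wavelet scale
#'
#' The oscillation frequency associated with a wavelet scale \eqn{a} is
#' \eqn{f = f_c / (a \, \Delta t)}, where \eqn{\Delta t} is the digitization
#' interval.
#'
#' @param scale Positive wavelet scale (dimensionless).
#' @param sample_interval Digitization interval \eqn{\Delta t} in seconds.
#' @param center_frequency Mother-wavelet center frequency \eqn{f_c} in Hz.
#' @return Pseudo-frequency in Hz.
#' @examples
#' pseudo_frequency(100, 0.002, 1)  # 5 Hz
#' @export
pseudo_frequency <- function(scale, sample_interval, center_frequency = 1) {
  if (!is.numeric(scale) || any(!is.finite(scale)) || any(scale <= 0)) {
    stop("`scale` must be positive and finite", call. = FALSE)
  }
  stop_if_not_scalar_pos(sample_interval, "sample_interval")
  stop_if_not_scalar_pos(center_frequency, "center_frequency")
  center_frequency / (scale * sample_interval)
}

#' Scales realizing a set of analysis frequencies
#'
#' Inverts the pseudo-frequency relation: the scale at which the wavelet's
#' pseudo-frequency equals a requested analysis frequency \eqn{f} is
#' \eqn{a = f_c / (f \, \Delta t)}. Scales come back strictly decreasing when
#' the frequencies are strictly increasing.
#'
#' @param spec A [wavelet_spec()].
#' @param sample_interval Digitization interval in seconds.
#' @return Numeric vector of scales, one per analysis frequency.
#' @examples
#' scales_for_frequencies(wavelet_spec(), 0.002)
#' @export
scales_for_frequencies <- function(spec, sample_interval) {
  stopifnot(inherits(spec, "wavelet_spec"))
  stop_if_not_scalar_pos(sample_interval, "sample_interval")
  spec$center_frequency / (spec$frequencies * sample_interval)
}

# Daughter wavelet sampled at integer offsets k = -L..L; argument u = k / a.
# Returned with L2-style 1/sqrt(a) normalization. Truncated at 4 envelope SDs.
morlet_daughter <- function(scale, center_frequency, bandwidth,
                            trunc_sd = 4) {
  sigma_u <- sqrt(bandwidth / 2)
  L <- ceiling(trunc_sd * sigma_u * scale)
  u <- seq(-L, L) / scale
  psi <- (pi * bandwidth)^(-0.5) *
    exp(2i * pi * center_frequency * u) * exp(-u^2 / bandwidth)
  list(values = psi / sqrt(scale), halfwidth = as.integer(L))
}

#' Complex Morlet scalogram of a single-channel signal
#'
#' Convolves the signal with a complex Morlet wavelet at the scales matching
#' `spec$frequencies` and returns power as the squared modulus of the
#' (complex) wavelet coefficients. Convolution is computed in the frequency
#' domain with zero padding; the per-scale half-width of the truncated
#' wavelet is recorded as a cone of influence, inside which coefficients are
#' contaminated by the zero-padded edges.
#'
#' @param x Real-valued signal (one channel, one epoch).
#' @param sample_interval Digitization interval in seconds.
#' @param spec A [wavelet_spec()].
#' @return An object of class `scalogram`: a list with `power` (matrix,
#'   scales by time), `scales`, `pseudo_frequencies`, `sample_interval`,
#'   `coi_halfwidth` (integer vector, per scale, in samples) and `n_time`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 0.002))
#' sg <- morlet_scalogram(x, 0.002)
#' sg$pseudo_frequencies
#' @export
morlet_scalogram <- function(x, sample_interval, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  stop_if_not_scalar_pos(sample_interval, "sample_interval")
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be a finite numeric signal", call. = FALSE)
  }
  n <- length(x)
  scales <- scales_for_frequencies(spec, sample_interval)
  daughters <- lapply(scales, morlet_daughter,
                      center_frequency = spec$center_frequency,
                      bandwidth = spec$bandwidth)
  max_len <- max(vapply(daughters, function(d) 2L * d$halfwidth + 1L,
                        integer(1)))
  min_n <- 4L * max_len
  if (n < min_n) {
    stop(sprintf(paste0("signal too short for the requested scales: ",
                        "%d samples given, minimum is %d ",
                        "(4 x the longest truncated wavelet)"), n, min_n),
         call. = FALSE)
  }
  nfft <- stats::nextn(n + max_len - 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(0, nrow = length(scales), ncol = n)
  for (s in seq_along(scales)) {
    w <- daughters[[s]]$values
    L <- daughters[[s]]$halfwidth
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    y <- stats::fft(X * W, inverse = TRUE) / nfft
    coef <- y[(L + 1L):(L + n)]
    power[s, ] <- Mod(coef)^2
  }
  structure(
    list(power = power,
         scales = scales,
         pseudo_frequencies = spec$frequencies,
         sample_interval = sample_interval,
         coi_halfwidth = vapply(daughters, `[[`, integer(1), "halfwidth"),
         n_time = n),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("Scalogram: %d scales x %d samples (dt = %g s)\n",
              nrow(x$power), x$n_time, x$sample_interval))
  cat(sprintf("  pseudo-frequencies: %s Hz\n",
              paste(signif(x$pseudo_frequencies, 4), collapse = ", ")))
  invisible(x)
}
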