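# Synthetic multichannel EEG with known ground truth: 1/f Gaussian
# background plus band-limited oscillations whose amplitude envelopes are
# gated by a renewal process of bursts. The regularity of that renewal
# process (its Gamma shape) is the ground-truth quantity that downstream
# inter-departure fitting should track, and the condition effect perturbs
# it — not overall power — on designated channels.

#' Synthetic-EEG study specification
#'
#' Defaults emulate a resting-state pediatric study design: 56 subjects, 128
#' channels, two paired conditions recorded in alternating 30 s epochs (4
#' per condition) at 500 Hz. Any field can be reduced for desk-scale
#' simulations.
#'
#' The default oscillation bands are an alpha-dominant resting profile:
#' 10 Hz at 6 times the unit-SD background and 20 Hz at 2 times it, with
#' burst onsets 0.8 s apart on average. Bursts are kept sparse enough, and
#' bands strong enough, that envelope troughs are resolvable at the
#' wavelet's temporal resolution — the condition that makes the envelope's
#' renewal regularity identifiable from downstream inter-departure fits.
#'
#' @param n_subjects,n_channels,n_conditions,epochs_per_condition Study
#'   dimensions.
#' @param epoch_duration Epoch length in seconds.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   oscillation band center.
#' @param bands Data.frame with columns `center_hz` and `amplitude` (burst
#'   oscillation bands riding on the background).
#' @param noise_exponent Spectral slope of the 1/f background (power
#'   spectral density proportional to `f^-noise_exponent`).
#' @param burst_shape Gamma shape of the inter-burst renewal intervals
#'   (envelope regularity); higher is more regular.
#' @param burst_mean_interval Mean inter-burst interval in seconds.
#' @param effect_channels Integer channel indices carrying the condition
#'   effect.
#' @param effect_magnitude Fractional change of burst-envelope regularity
#'   (the renewal shape) in condition 2 on `effect_channels`; 0 means no
#'   effect anywhere.
#' @param condition_labels Labels of the alternating conditions.
#' @param seed Master RNG seed for the whole study.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 56, n_channels = 128, n_conditions = 2,
                       epochs_per_condition = 4, epoch_duration = 30,
                       sampling_rate = 500,
                       bands = data.frame(center_hz = c(10, 20),
                                          amplitude = c(6.0, 2.0)),
                       noise_exponent = 1, burst_shape = 2,
                       burst_mean_interval = 0.8,
                       effect_channels = integer(0), effect_magnitude = 0,
                       condition_labels = c("eyes_closed", "eyes_open"),
                       seed = 1) {
  stopifnot(n_subjects >= 1, n_channels >= 1, n_conditions == 2,
            epochs_per_condition >= 1, epoch_duration > 0,
            sampling_rate > 0, is.data.frame(bands),
            all(c("center_hz", "amplitude") %in% names(bands)),
            all(bands$amplitude >= 0), all(bands$center_hz > 0),
            burst_shape > 0, burst_mean_interval > 0,
            effect_magnitude > -1,
            length(condition_labels) == n_conditions)
  if (sampling_rate <= 2 * max(bands$center_hz)) {
    stop("sampling_rate must exceed twice the highest band center",
         call. = FALSE)
  }
  effect_channels <- as.integer(effect_channels)
  if (length(effect_channels) &&
      (any(effect_channels < 1) || any(effect_channels > n_channels))) {
    stop("`effect_channels` must index existing channels", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_channels = as.integer(n_channels),
         n_conditions = as.integer(n_conditions),
         epochs_per_condition = as.integer(epochs_per_condition),
         epoch_duration = epoch_duration,
         sampling_rate = sampling_rate,
         bands = bands,
         noise_exponent = noise_exponent,
         burst_shape = burst_shape,
         burst_mean_interval = burst_mean_interval,
         effect_channels = effect_channels,
         effect_magnitude = effect_magnitude,
         condition_labels = condition_labels,
         seed = seed),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic EEG spec: %d subjects x %d channels, ",
                     "%d x %d epochs of %g s at %g Hz\n"),
              x$n_subjects, x$n_channels, x$n_conditions,
              x$epochs_per_condition, x$epoch_duration, x$sampling_rate))
  cat(sprintf("  effect: %g on %d channel(s)\n", x$effect_magnitude,
              length(x$effect_channels)))
  invisible(x)
}

#' 1/f Gaussian background noise
#'
#' Shapes white Gaussian noise in the frequency domain so the power
#' spectral density falls off as `f^-exponent`, then normalizes to unit
#' standard deviation. Uses the current RNG state (seed upstream).
#'
#' @param n Number of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param exponent Spectral slope (1 = pink noise).
#' @return Numeric vector of length `n`, zero mean, unit SD.
#' @export
onef_noise <- function(n, sampling_rate, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- seq(0, n - 1) * sampling_rate / n
  freqs <- pmin(freqs, sampling_rate - freqs)  # two-sided
  gain <- c(0, freqs[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Burst-gated oscillation: renewal process of burst onsets with
# Gamma(shape, mean = mean_interval) intervals; each burst contributes a
# raised-cosine amplitude bump of half-width `width` seconds.
burst_envelope <- function(n, sampling_rate, shape, mean_interval, width) {
  t_max <- n / sampling_rate
  # draw enough intervals to cover the epoch plus margins
  n_draw <- ceiling((t_max + 4 * width) / mean_interval * 3) + 20
  gaps <- stats::rgamma(n_draw, shape = shape,
                        scale = mean_interval / shape)
  onsets <- cumsum(gaps) - stats::runif(1, 0, mean_interval)
  onsets <- onsets[onsets > -width & onsets < t_max + width]
  env <- numeric(n)
  half_w_samp <- width * sampling_rate
  for (tb in onsets) {
    cs <- tb * sampling_rate
    lo <- max(1, ceiling(cs - half_w_samp))
    hi <- min(n, floor(cs + half_w_samp))
    if (lo > hi) next
    u <- ((lo:hi) - cs) / half_w_samp
    env[lo:hi] <- env[lo:hi] + 0.5 * (1 + cos(pi * u))
  }
  env
}

# One channel-epoch of synthetic EEG.
synth_channel_epoch <- function(spec, shape_mult) {
  fs <- spec$sampling_rate
  n <- round(spec$epoch_duration * fs)
  tt <- seq_len(n) / fs
  x <- onef_noise(n, fs, spec$noise_exponent)
  for (b in seq_len(nrow(spec$bands))) {
    f <- spec$bands$center_hz[b]
    amp <- spec$bands$amplitude[b]
    if (amp == 0) next
    env <- burst_envelope(n, fs, spec$burst_shape * shape_mult,
                          spec$burst_mean_interval, width = 2 / f)
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + amp * env * sin(2 * pi * f * tt + phase)
  }
  x
}

#' Generate a synthetic EEG study
#'
#' Every channel is 1/f Gaussian background plus burst-gated band-limited
#' oscillations. On `effect_channels`, epochs of the second condition use a
#' burst-renewal shape multiplied by `1 + effect_magnitude`, changing
#' envelope regularity without changing band power. Conditions alternate
#' across epochs, as in an eyes-closed / eyes-open resting protocol.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return An `eeg_study`: list of [epoched_recording()]s, one per subject.
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$epoch_duration * fs)
  n_epochs <- spec$n_conditions * spec$epochs_per_condition
  cond_seq <- rep(spec$condition_labels,
                  times = spec$epochs_per_condition)  # alternating
  recs <- lapply(seq_len(spec$n_subjects), function(si) {
    with_seed(derive_seed(spec$seed, si), {
      # modest between-subject variation in envelope regularity
      subj_mult <- exp(stats::rnorm(1, 0, 0.1))
      dat <- array(0, dim = c(spec$n_channels, n, n_epochs))
      for (ep in seq_len(n_epochs)) {
        cond2 <- cond_seq[ep] == spec$condition_labels[2]
        for (ch in seq_len(spec$n_channels)) {
          mult <- subj_mult
          if (cond2 && ch %in% spec$effect_channels) {
            mult <- mult * (1 + spec$effect_magnitude)
          }
          dat[ch, , ep] <- synth_channel_epoch(spec, mult)
        }
      }
      epoched_recording(dat, sampling_rate = fs, conditions = cond_seq,
                        subject = sprintf("s%02d", si))
    })
  })
  as_eeg_study(recs)
}

#' Draws from a Gamma distribution as an IDT sample
#'
#' Fixture generator for distribution-fitting: `n` independent draws from
#' Gamma(`shape`, `scale`), reproducible from `seed`.
#'
#' @param shape,scale Gamma parameters (both positive).
#' @param n Number of draws.
#' @param seed Explicit RNG seed.
#' @return An `idt_sample`-like numeric vector (plain vector; pass to
#'   fitting functions directly).
#' @export
generate_gamma_sample <- function(shape, scale, n, seed) {
  stop_if_not_scalar_pos(shape, "shape")
  stop_if_not_scalar_pos(scale, "scale")
  with_seed(seed, stats::rgamma(as.integer(n), shape = shape, scale = scale))
}

#' Band-pass, trim and demean an epoched recording
#'
#' The standard preprocessing applied before scalogram computation: a
#' zero-phase Butterworth band-pass (order 2, applied forward and backward),
#' an optional zero-phase notch (4 Hz-wide band-stop), trimming to the
#' middle window of each epoch to avoid boundary contamination, and
#' per-epoch temporal mean subtraction.
#'
#' @param recording An [epoched_recording()] or `eeg_study`.
#' @param band Band-pass edges in Hz (default `c(0.5, 55)`).
#' @param notch Notch center frequency in Hz, or `NULL` to skip
#'   (default 60).
#' @param trim Window in seconds kept from each epoch (default `c(5, 25)`,
#'   the middle 20 s of a 30 s epoch), or `NULL` to keep everything.
#' @param demean Subtract each epoch's temporal mean (default `TRUE`).
#' @return Object of the same class with processed data.
#' @export
preprocess_epochs <- function(recording, band = c(0.5, 55), notch = 60,
                              trim = c(5, 25), demean = TRUE) {
  if (inherits(recording, "eeg_study")) {
    return(as_eeg_study(lapply(recording, preprocess_epochs, band = band,
                               notch = notch, trim = trim,
                               demean = demean)))
  }
  stopifnot(inherits(recording, "epoched_recording"))
  fs <- recording$sampling_rate
  n <- dim(recording$data)[2]
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  ns <- if (!is.null(notch)) {
    signal::butter(2, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
  } else NULL
  if (!is.null(trim)) {
    keep <- (round(trim[1] * fs) + 1L):round(trim[2] * fs)
    if (max(keep) > n) {
      stop(sprintf("epoch (%d samples) shorter than the trim window %g-%g s",
                   n, trim[1], trim[2]), call. = FALSE)
    }
  } else {
    keep <- seq_len(n)
  }
  out <- array(0, dim = c(dim(recording$data)[1], length(keep),
                          dim(recording$data)[3]))
  for (ep in seq_len(dim(recording$data)[3])) {
    for (ch in seq_len(dim(recording$data)[1])) {
      x <- signal::filtfilt(bp, recording$data[ch, , ep])
      if (!is.null(ns)) x <- signal::filtfilt(ns, x)
      x <- x[keep]
      if (demean) x <- x - mean(x)
      out[ch, , ep] <- x
    }
  }
  epoched_recording(out, sampling_rate = fs,
                    conditions = recording$conditions,
                    channel_names = recording$channel_names,
                    subject = recording$subject)
}

#' Generate and preprocess a synthetic study in one step
#'
#' @param spec A [synth_spec()].
#' @param ... Passed to [preprocess_epochs()].
#' @return A preprocessed `eeg_study`.
#' @export
generate_preprocessed_epochs <- function(spec, ...) {
  preprocess_epochs(generate_eeg(spec), ...)
}
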