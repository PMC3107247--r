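#' Detect message departures as prominent troughs of scalogram power
#'
#' Departure times are the local minima of a scalogram power series. To keep
#' minute, insignificant dips from being selected, each candidate minimum
#' must have a topographic prominence of at least `threshold_ratio` times the
#' range (max minus min) of the series: on both sides, power must rise by at
#' least that much before a strictly deeper minimum is reached. A flat run of
#' equal minimal values yields a single event at the run midpoint (rounded
#' down); runs touching either end of the series are excluded.
#'
#' @param power_series Non-negative finite numeric vector (one channel, one
#'   scale, one epoch of scalogram power).
#' @param threshold_ratio Prominence threshold as a fraction of the series
#'   range, in `[0, 1)`. Default 0.05.
#' @return An object of class `departure_train`: list with `events`
#'   (1-based sample indices, strictly increasing), `n_time` and
#'   `threshold_ratio`. A constant series yields an empty train.
#' @examples
#' detect_departures(c(5, 1, 5, 4.9, 5, 1, 5))$events  # 2 and 6
#' @export
detect_departures <- function(power_series, threshold_ratio = 0.05) {
  if (!is.numeric(power_series) || length(power_series) < 3L) {
    stop("`power_series` must be numeric with at least 3 samples",
         call. = FALSE)
  }
  if (any(!is.finite(power_series))) {
    stop("`power_series` contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(threshold_ratio) || length(threshold_ratio) != 1L ||
      threshold_ratio < 0 || threshold_ratio >= 1) {
    stop("`threshold_ratio` must be a single number in [0, 1)",
         call. = FALSE)
  }
  events <- cpp_find_troughs(as.numeric(power_series), threshold_ratio)
  structure(
    list(events = events,
         n_time = length(power_series),
         threshold_ratio = threshold_ratio),
    class = "departure_train"
  )
}

#' @export
print.departure_train <- function(x, ...) {
  cat(sprintf("Departure train: %d events over %d samples (threshold %g)\n",
              length(x$events), x$n_time, x$threshold_ratio))
  invisible(x)
}

#' Inter-departure times of a departure train
#'
#' The delay tau between successive departures, in digitization intervals
#' (samples). Use [idt_ms()] to convert to milliseconds.
#'
#' @param train A [detect_departures()] result, or a strictly increasing
#'   integer vector of event indices.
#' @return An object of class `idt_sample`: list with `intervals` (positive
#'   durations in samples) and `n`.
#' @examples
#' inter_departure_times(c(10, 30, 35))$intervals  # 20 and 5
#' @export
inter_departure_times <- function(train) {
  events <- if (inherits(train, "departure_train")) train$events else train
  if (!is.numeric(events) || length(events) < 2L) {
    stop("need at least 2 departure events to form intervals", call. = FALSE)
  }
  if (is.unsorted(events, strictly = TRUE)) {
    stop("event indices must be strictly increasing", call. = FALSE)
  }
  idt_sample(diff(as.numeric(events)))
}

#' Construct an inter-departure time sample
#'
#' @param intervals Positive durations in digitization intervals.
#' @return An `idt_sample` object.
#' @export
idt_sample <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) && (any(!is.finite(intervals)) ||
                            any(intervals < 1))) {
    stop("intervals must be >= 1 digitization interval", call. = FALSE)
  }
  structure(list(intervals = intervals, n = length(intervals)),
            class = "idt_sample")
}

#' @export
print.idt_sample <- function(x, ...) {
  cat(sprintf("IDT sample: n = %d, mean = %.2f samples\n",
              x$n, mean(x$intervals)))
  invisible(x)
}

#' Convert inter-departure times from samples to milliseconds
#'
#' @param sample An `idt_sample` or numeric vector of intervals in samples.
#' @param sample_interval Digitization interval in seconds.
#' @return Numeric vector of intervals in ms.
#' @export
idt_ms <- function(sample, sample_interval) {
  stop_if_not_scalar_pos(sample_interval, "sample_interval")
  iv <- if (inherits(sample, "idt_sample")) sample$intervals else sample
  iv * sample_interval * 1000
}

# Detect departures on one scalogram, dropping events inside the cone of
# influence when requested, and return per-scale event index lists.
# Detection runs on the amplitude series (sqrt of power): trough locations
# are identical under the monotone square, but the prominence threshold is
# taken as a ratio of the range of the scalogram *amplitude*, which keeps a
# few extreme power peaks from inflating the normalization.
scalogram_departures <- function(sg, threshold_ratio = 0.05,
                                 drop_edge_events = TRUE) {
  stopifnot(inherits(sg, "scalogram"))
  lapply(seq_along(sg$scales), function(s) {
    ev <- detect_departures(sqrt(sg$power[s, ]), threshold_ratio)$events
    if (drop_edge_events && length(ev)) {
      L <- sg$coi_halfwidth[s]
      ev <- ev[ev > L & ev <= sg$n_time - L]
    }
    ev
  })
}

#' Extract the inter-departure time table of a study
#'
#' Runs the scalogram and trough-detection stages over every subject,
#' condition, channel, epoch and analysis frequency of a study, pools the
#' per-epoch intervals of each (subject, condition, channel, frequency) cell
#' into one sample, and returns them in long form. No interval ever spans an
#' epoch boundary: differencing is done within each epoch before pooling.
#'
#' @param study An `eeg_study` (list of [epoched_recording()]s) or a single
#'   `epoched_recording`.
#' @param spec A [wavelet_spec()].
#' @param threshold_ratio Prominence threshold passed to
#'   [detect_departures()]. Default 0.05.
#' @param drop_edge_events Drop departures inside the per-scale cone of
#'   influence (default `TRUE`); boundary troughs there are artifacts of
#'   zero padding.
#' @return A data.frame with columns `subject`, `condition`, `channel`,
#'   `frequency_hz`, `tau_samples` (one row per interval). Cells with fewer
#'   than two events in every epoch simply contribute no rows.
#' @export
extract_idt_table <- function(study, spec = wavelet_spec(),
                              threshold_ratio = 0.05,
                              drop_edge_events = TRUE) {
  study <- as_eeg_study(study)
  rows <- list()
  for (rec in study) {
    nch <- dim(rec$data)[1]
    nep <- dim(rec$data)[3]
    dt <- 1 / rec$sampling_rate
    for (ch in seq_len(nch)) {
      # per (condition, frequency): list of pooled intervals
      pooled <- list()
      for (ep in seq_len(nep)) {
        sg <- morlet_scalogram(rec$data[ch, , ep], dt, spec)
        evs <- scalogram_departures(sg, threshold_ratio, drop_edge_events)
        for (s in seq_along(evs)) {
          if (length(evs[[s]]) >= 2L) {
            key <- paste(rec$conditions[ep], s, sep = "\r")
            pooled[[key]] <- c(pooled[[key]], diff(evs[[s]]))
          }
        }
      }
      for (key in names(pooled)) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        s <- as.integer(parts[2])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = rec$subject,
          condition = parts[1],
          channel = rec$channel_names[ch],
          frequency_hz = spec$frequencies[s],
          tau_samples = as.numeric(pooled[[key]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(), condition = character(),
                      channel = character(), frequency_hz = numeric(),
                      tau_samples = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pull one cell of an IDT table as an `idt_sample`
#'
#' @param idt_table Result of [extract_idt_table()].
#' @param subject,condition,channel,frequency_hz Cell key.
#' @return An `idt_sample` (possibly empty).
#' @export
idt_cell <- function(idt_table, subject, condition, channel, frequency_hz) {
  sel <- idt_table$subject == subject &
    idt_table$condition == condition &
    idt_table$channel == channel &
    idt_table$frequency_hz == frequency_hz
  idt_sample(idt_table$tau_samples[sel])
}
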