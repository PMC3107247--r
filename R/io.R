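# Recording containers and file I/O: minimal vanilla EDF (16-bit) and a
# plain-text matrix + JSON metadata format. Condition labels are not
# representable in plain EDF, so they travel in a text sidecar.

#' Epoched multichannel recording
#'
#' @param data Numeric array `channels x samples x epochs`, or a
#'   `channels x samples` matrix for a single epoch.
#' @param sampling_rate Sampling rate in Hz.
#' @param conditions Character vector of per-epoch condition labels.
#' @param channel_names Optional channel labels (default `ch001`, ...).
#' @param subject Subject identifier.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, sampling_rate, conditions,
                              channel_names = NULL, subject = "s01") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  conditions <- as.character(conditions)
  if (length(conditions) != dim(data)[3]) {
    stop("need one condition label per epoch", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%03d", seq_len(dim(data)[1]))
  }
  stopifnot(length(channel_names) == dim(data)[1])
  structure(
    list(data = data, sampling_rate = sampling_rate,
         conditions = conditions, channel_names = channel_names,
         subject = subject),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("Epoched recording '%s': %d channels x %d samples x ",
                     "%d epochs at %g Hz\n"),
              x$subject, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Coerce to a multi-subject study
#'
#' @param x An `eeg_study`, a list of recordings, or one
#'   `epoched_recording`.
#' @return An `eeg_study` (list of `epoched_recording`s).
#' @export
as_eeg_study <- function(x) {
  if (inherits(x, "eeg_study")) return(x)
  if (inherits(x, "epoched_recording")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "epoched_recording")))
  names(x) <- vapply(x, `[[`, character(1), "subject")
  structure(x, class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("EEG study: %d subject(s)\n", length(x)))
  invisible(x)
}

# ---- EDF ----------------------------------------------------------------

# Fixed-width ASCII field, left-justified, space padded.
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF field overflow: ", s, call. = FALSE)
  formatC(s, width = -width)
}

# Numeric field fitting 8 ASCII chars.
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= 8) return(edf_field(s, 8))
  }
  stop("cannot format number in 8 chars: ", x, call. = FALSE)
}

#' Write an epoched recording as an EDF file
#'
#' Plain (vanilla) EDF: one data record per epoch, 16-bit samples scaled
#' per channel between the channel's physical min and max. Condition labels
#' have no slot in the EDF header and are written to a plain-text sidecar
#' `<path>.labels`, one label per line.
#'
#' @param recording An [epoched_recording()].
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "epoched_recording"))
  d <- dim(recording$data)
  nch <- d[1]; nsamp <- d[2]; nrec <- d[3]
  pmin <- apply(recording$data, 1, min)
  pmax <- apply(recording$data, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # Physical extrema must survive an 8-char ASCII round trip, or samples at
  # the edge of the range would fall outside the reconstructed scale.
  pmin <- as.numeric(sapply(pmin, function(v) trimws(edf_num8(v)))) -
    (pmax - pmin) * 1e-6
  pmax <- as.numeric(sapply(pmax, function(v) trimws(edf_num8(v)))) +
    (pmax - pmin) * 1e-6
  dmin <- -32768; dmax <- 32767
  header_bytes <- 256L + 256L * nch
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field(recording$subject, 80))
  wr(edf_field("eegtraffic recording", 80))
  wr(edf_field("01.01.00", 8))
  wr(edf_field("00.00.00", 8))
  wr(edf_field(header_bytes, 8))
  wr(edf_field("", 44))
  wr(edf_field(nrec, 8))
  wr(edf_num8(nsamp / recording$sampling_rate))
  wr(edf_field(nch, 4))
  for (ch in seq_len(nch)) wr(edf_field(recording$channel_names[ch], 16))
  for (ch in seq_len(nch)) wr(edf_field("", 80))            # transducer
  for (ch in seq_len(nch)) wr(edf_field("uV", 8))           # dimension
  for (ch in seq_len(nch)) wr(edf_num8(pmin[ch]))
  for (ch in seq_len(nch)) wr(edf_num8(pmax[ch]))
  for (ch in seq_len(nch)) wr(edf_field(dmin, 8))
  for (ch in seq_len(nch)) wr(edf_field(dmax, 8))
  for (ch in seq_len(nch)) wr(edf_field("", 80))            # prefilter
  for (ch in seq_len(nch)) wr(edf_field(nsamp, 8))
  for (ch in seq_len(nch)) wr(edf_field("", 32))            # reserved
  for (rec in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      x <- recording$data[ch, , rec]
      dig <- round((x - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                     (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  writeLines(recording$conditions, paste0(path, ".labels"))
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any vanilla EDF)
#'
#' Epochs are taken to be the EDF data records. Condition labels are read
#' from the `<path>.labels` sidecar if present, otherwise they must be
#' supplied; reading without any labels is an error because downstream
#' analyses are condition-paired.
#'
#' @param path EDF file path.
#' @param conditions Optional per-epoch labels overriding the sidecar.
#' @param subject Optional subject id overriding the header patient field.
#' @return An [epoched_recording()].
#' @export
read_edf <- function(path, conditions = NULL, subject = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    raw <- readChar(con, nc, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < nc) {
      stop("EDF parse error: truncated header in ", path, call. = FALSE)
    }
    trimws(raw)
  }
  rd(8)                                  # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nrec) || is.na(duration) || is.na(nch) || nch < 1) {
    stop("EDF parse error: malformed fixed header in ", path, call. = FALSE)
  }
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF parse error: differing samples per record not supported",
         call. = FALSE)
  }
  nsamp <- spr[1]
  expected <- header_bytes + as.double(nrec) * nch * nsamp * 2
  if (file.size(path) < expected) {
    stop(sprintf("EDF parse error: file truncated (%d bytes, expected %d)",
                 file.size(path), as.integer(expected)), call. = FALSE)
  }
  dat <- array(0, dim = c(nch, nsamp, nrec))
  for (rec in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = nsamp, size = 2L, signed = TRUE,
                     endian = "little")
      dat[ch, , rec] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
    }
  }
  if (is.null(conditions)) {
    sidecar <- paste0(path, ".labels")
    if (file.exists(sidecar)) {
      conditions <- readLines(sidecar)
    } else {
      stop(paste0("missing condition labels: supply `conditions` or a ",
                  "`<path>.labels` sidecar"), call. = FALSE)
    }
  }
  epoched_recording(dat, sampling_rate = nsamp / duration,
                    conditions = conditions, channel_names = labels,
                    subject = if (is.null(subject)) patient else subject)
}

# ---- plain-text matrix + metadata ---------------------------------------

#' Write a recording as TSV matrix plus JSON metadata
#'
#' Samples are written full precision as TSV (rows = samples with epochs
#' stacked, columns = channels); a `<path>.json` sidecar holds the sampling
#' rate, epoch structure, condition labels, channel names and subject id.
#'
#' @param recording An [epoched_recording()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(recording, path) {
  stopifnot(inherits(recording, "epoched_recording"))
  d <- dim(recording$data)
  stacked <- do.call(rbind, lapply(seq_len(d[3]), function(ep) {
    t(recording$data[, , ep, drop = TRUE])
  }))
  utils::write.table(format(stacked, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate,
               n_channels = d[1], n_samples = d[2], n_epochs = d[3],
               conditions = recording$conditions,
               channel_names = recording$channel_names,
               subject = recording$subject)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TSV + JSON recording written by [write_recording_matrix()]
#'
#' @param path TSV path (with `<path>.json` metadata sidecar).
#' @return An [epoched_recording()].
#' @export
read_recording_matrix <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop("recording files not found: need both ", path, " and ", meta_path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$conditions)) {
    stop("missing condition labels in ", meta_path, call. = FALSE)
  }
  stacked <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(stacked) != meta$n_samples * meta$n_epochs ||
      ncol(stacked) != meta$n_channels) {
    stop(sprintf(paste0("parse error in %s: %d x %d values, metadata ",
                        "promises %d x %d"),
                 path, nrow(stacked), ncol(stacked),
                 meta$n_samples * meta$n_epochs, meta$n_channels),
         call. = FALSE)
  }
  dat <- array(0, dim = c(meta$n_channels, meta$n_samples, meta$n_epochs))
  for (ep in seq_len(meta$n_epochs)) {
    rows <- ((ep - 1L) * meta$n_samples + 1L):(ep * meta$n_samples)
    dat[, , ep] <- t(stacked[rows, , drop = FALSE])
  }
  epoched_recording(dat, meta$sampling_rate, meta$conditions,
                    meta$channel_names, meta$subject)
}

#' Read a recording, dispatching on format
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.edf` vs anything else),
#'   `"edf"` or `"matrix"`.
#' @param ... Passed to the format reader.
#' @return An [epoched_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "matrix"
  }
  switch(format, edf = read_edf(path, ...), matrix = read_recording_matrix(path))
}
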