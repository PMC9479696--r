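#' Event record: one utterance of spike events
#'
#' The event-based representation used by the 700-channel cochlear-encoded
#' speech datasets: an array of spike times (seconds) with the emitting
#' channel index for each event, plus an integer class label.
#'
#' @param times numeric vector of spike times in seconds (non-negative,
#'   finite).
#' @param units integer vector of 0-based channel indices, same length as
#'   \code{times}.
#' @param label integer class label.
#' @param n_channels total channel count (default 700).
#' @return Object of class \code{"event_record"}.
#' @export
event_record <- function(times, units, label, n_channels = 700L) {
  times <- as.numeric(times)
  units <- as.integer(units)
  if (length(times) != length(units)) {
    stop("times and units must have equal lengths", call. = FALSE)
  }
  if (length(times) && (any(!is.finite(times)) || any(times < 0))) {
    stop("spike times must be finite and non-negative", call. = FALSE)
  }
  if (length(units) && (any(units < 0L) || any(units >= n_channels))) {
    stop("unit indices must lie in [0, n_channels)", call. = FALSE)
  }
  structure(list(times = times, units = units, label = as.integer(label),
                 n_channels = as.integer(n_channels)),
            class = "event_record")
}

#' Read / write event datasets
#'
#' Plain-text container for collections of [event_record()]s, mirroring
#' the grouped layout of the published spiking speech datasets: a
#' \code{spikes} group holding per-utterance \code{times} and \code{units}
#' arrays, plus a \code{labels} array and the channel count. Round-trips
#' losslessly.
#'
#' @param path file path (JSON).
#' @return \code{read_event_file}: a list of \code{"event_record"}s.
#' @export
read_event_file <- function(path) {
  if (!file.exists(path)) {
    stop("event file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  for (key in c("spikes", "labels", "n_channels")) {
    if (is.null(obj[[key]])) {
      stop("malformed event file: missing key '", key, "'", call. = FALSE)
    }
  }
  for (key in c("times", "units")) {
    if (is.null(obj$spikes[[key]])) {
      stop("malformed event file: missing key 'spikes/", key, "'",
           call. = FALSE)
    }
  }
  n <- length(obj$labels)
  if (length(obj$spikes$times) != n || length(obj$spikes$units) != n) {
    stop("malformed event file: spikes/labels lengths disagree",
         call. = FALSE)
  }
  lapply(seq_len(n), function(i) {
    event_record(times = unlist(obj$spikes$times[[i]], use.names = FALSE) %||%
                   numeric(0),
                 units = unlist(obj$spikes$units[[i]], use.names = FALSE) %||%
                   integer(0),
                 label = obj$labels[[i]],
                 n_channels = obj$n_channels)
  })
}

#' @rdname read_event_file
#' @param records list of [event_record()]s.
#' @export
write_event_file <- function(records, path) {
  if (inherits(records, "event_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "event_record")))
  n_channels <- unique(vapply(records, `[[`, integer(1), "n_channels"))
  if (length(n_channels) != 1L) {
    stop("all records must share one channel count", call. = FALSE)
  }
  obj <- list(
    spikes = list(
      times = lapply(records, function(r) as.numeric(r$times)),
      units = lapply(records, function(r) as.integer(r$units))
    ),
    labels = vapply(records, `[[`, integer(1), "label"),
    n_channels = n_channels
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Bin spike events onto a channel x time grid
#'
#' Maps each event at time t to bin \code{floor(t / duration * n_steps)},
#' clipping events exactly at the endpoint into the last bin, and
#' accumulates counts per (bin, channel). The default binarized raster
#' clips counts to \{0, 1\}; with \code{binarize = FALSE} the total event
#' count is conserved.
#'
#' @param record an [event_record()].
#' @param n_steps number of time bins T (default 100).
#' @param n_channels channel count F (default from the record).
#' @param binarize clip bin counts to 0/1 (default TRUE).
#' @param duration utterance duration in seconds; defaults to the latest
#'   event time.
#' @return T x F numeric matrix of class \code{"spike_raster"} with the
#'   label kept as attribute \code{"label"}.
#' @export
bin_events <- function(record, n_steps = 100L, n_channels = NULL,
                       binarize = TRUE, duration = NULL) {
  stopifnot(inherits(record, "event_record"), n_steps >= 1)
  n_channels <- as.integer(n_channels %||% record$n_channels)
  grid <- matrix(0, n_steps, n_channels)
  if (length(record$times)) {
    duration <- duration %||% max(record$times)
    if (duration <= 0) duration <- 1
    bins <- pmin(floor(record$times / duration * n_steps), n_steps - 1L) + 1L
    for (i in seq_along(bins)) {
      ch <- record$units[i] + 1L
      grid[bins[i], ch] <- grid[bins[i], ch] + 1
    }
    if (binarize) grid <- pmin(grid, 1)
  }
  structure(grid, label = record$label, class = c("spike_raster", "matrix",
                                                  "array"))
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed audio: 8/16-bit integer and
#' 32-bit float PCM; multi-channel input is averaged to mono. Samples are
#' returned in \[-1, 1\].
#'
#' @param path WAV file path.
#' @return List with \code{samples} (numeric vector) and
#'   \code{sample_rate} (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw_fmt[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(raw_fmt[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536,
                                                       16777216)),
        bits = sum(as.integer(raw_fmt[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk before fmt", call. = FALSE)
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 1 && fmt$bits == 8) {
        samples <- (readBin(con, "integer", sz, 1, signed = FALSE) - 128) /
          128
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need 8/16-bit PCM or 32-bit float)",
             call. = FALSE)
      }
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(samples)) stop("WAV file has no data chunk", call. = FALSE)
  if (fmt$n_channels > 1) {
    samples <- colMeans(matrix(samples, fmt$n_channels))
  }
  list(samples = as.numeric(samples), sample_rate = fmt$sample_rate)
}

#' Mel filterbank matrix
#'
#' Triangular filters spaced uniformly on the mel scale
#' (\eqn{2595 \log_{10}(1 + f/700)}) between 0 Hz and Nyquist.
#'
#' @param n_mels number of filters.
#' @param n_fft FFT length.
#' @param sample_rate sampling rate (Hz).
#' @return (n_fft/2 + 1) x n_mels filter matrix, with filter center
#'   frequencies (Hz) as attribute \code{"centers"}.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2 + 1
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                 length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- seq(0, sample_rate / 2, length.out = n_bins)
  fb <- matrix(0, n_bins, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "centers") <- hz_pts[2:(n_mels + 1)]
  fb
}

#' Log-mel filterbank features from a waveform
#'
#' Standard acoustic front-end: pre-emphasis, Hamming-windowed short-time
#' FFT, mel-filtered power spectrum, log with a small floor. At the
#' defaults a 2.5 s utterance yields roughly 250 frames of 40 features.
#'
#' @param waveform numeric vector of mono samples.
#' @param sample_rate sampling rate in Hz.
#' @param n_mels number of mel filters (default 40).
#' @param window analysis window length in ms (default 25).
#' @param hop frame shift in ms (default 10).
#' @param preemphasis pre-emphasis coefficient (default 0.97).
#' @param floor lower clamp on mel energies before the log.
#' @return T x n_mels matrix of class \code{"feature_sequence"} with
#'   attributes \code{frame_shift_ms}, \code{window_ms} and the filterbank
#'   \code{centers}.
#' @export
wav_to_filterbank <- function(waveform, sample_rate, n_mels = 40,
                              window = 25, hop = 10, preemphasis = 0.97,
                              floor = 1e-10) {
  waveform <- as.numeric(waveform)
  if (!length(waveform)) stop("empty waveform", call. = FALSE)
  stopifnot(sample_rate > 0)
  win_n <- round(window / 1000 * sample_rate)
  hop_n <- max(1L, round(hop / 1000 * sample_rate))
  if (length(waveform) < win_n) {
    waveform <- c(waveform, numeric(win_n - length(waveform)))
  }
  x <- c(waveform[1], waveform[-1] - preemphasis *
           waveform[-length(waveform)])
  n_frames <- 1L + (length(x) - win_n) %/% hop_n
  n_fft <- 2^ceiling(log2(win_n))
  w <- signal::hamming(win_n)
  fb <- mel_filterbank(n_mels, n_fft, sample_rate)
  n_bins <- n_fft %/% 2 + 1
  frames <- matrix(0, n_frames, n_mels)
  for (i in seq_len(n_frames)) {
    seg <- x[((i - 1L) * hop_n + 1L):((i - 1L) * hop_n + win_n)] * w
    spec <- stats::fft(c(seg, numeric(n_fft - win_n)))[1:n_bins]
    power <- Mod(spec)^2
    frames[i, ] <- log(pmax(as.vector(power %*% fb), floor))
  }
  structure(frames, frame_shift_ms = hop, window_ms = window,
            centers = attr(fb, "centers"),
            class = c("feature_sequence", "matrix", "array"))
}

#' Poisson-process spike encoding of rate features
#'
#' Interprets non-negative features as firing rates: each (step, channel)
#' cell spikes independently with probability \code{min(1, gain * rate)}.
#'
#' @param features T x F matrix of non-negative rates.
#' @param gain scaling from rate to per-step spike probability.
#' @param seed optional integer seed for a reproducible draw.
#' @return Binary T x F \code{"spike_raster"} matrix.
#' @export
poisson_encode <- function(features, gain = 1, seed = NULL) {
  features <- as.matrix(features)
  if (any(features < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  p <- pmin(gain * features, 1)
  draw <- function() {
    (matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p) + 0
  }
  r <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(r, class = c("spike_raster", "matrix", "array"))
}
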