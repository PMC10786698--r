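# surface-EMG preprocessing and descriptive metrics

# zero-phase Butterworth band-pass, upper edge clipped below Nyquist
bandpass_zero_phase <- function(x, fs, band) {
  if (length(x) == 0L) stop_param("empty channel")
  if (band[1] >= band[2]) stop_param("inverted filter band")
  if (fs <= 2 * band[1])
    stop_param("sampling rate too low for the band's lower edge")
  hi <- min(band[2], 0.45 * fs)  # realizable upper edge
  bf <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Preprocess an sEMG recording
#'
#' Per channel: zero-phase 4th-order Butterworth band-pass (default
#' 15-1000 Hz, the acquisition band; the upper edge is clipped to
#' `0.45 * fs` so the filter is realizable at a 2000 Hz sampling
#' rate), then mean subtraction so every channel is zero-mean.
#'
#' @param rec a [semg_recording()].
#' @param band numeric length-2 band in Hz; default `c(15, 1000)`.
#' @return a preprocessed [semg_recording()]; channel means are within
#'   1e-9 of zero.
#' @export
semg_preprocess <- function(rec, band = c(15, 1000)) {
  stopifnot(inherits(rec, "semg_recording"))
  chans <- lapply(rec$channels, function(x) {
    y <- bandpass_zero_phase(x, rec$fs, band)
    y - mean(y)
  })
  semg_recording(chans, fs = rec$fs, gain = rec$gain,
                 posture = rec$posture)
}

# beat detection on a reference channel: peaks of the absolute
# band-passed reference above 4 robust SDs, 0.35 s refractory
detect_beats <- function(reference, fs) {
  env <- abs(bandpass_zero_phase(reference, fs, c(5, 40)))
  pk <- detect_peaks_series(env - stats::median(env), fs,
                            threshold_k = 4, min_interval_s = 0.35)
  pk$idx
}

#' Remove ECG contamination using a reference channel
#'
#' Heartbeats are detected on the reference channel (recorded high on
#' the trunk, where cardiac pickup dominates); around each beat a
#' template is formed by averaging the signal channel across beats,
#' and per beat a least-squares scaled copy of the template is
#' subtracted. If the reference shows no usable periodicity (fewer
#' than 3 beats), the signal is returned unchanged with attribute
#' `ecg_removed = FALSE` and a warning.
#'
#' @param sig numeric signal channel.
#' @param reference numeric reference channel of equal length.
#' @param fs sampling rate (Hz).
#' @param window_s template half-windows (s) before and after the
#'   beat center; default `c(0.06, 0.08)`.
#' @return cleaned signal with attribute `ecg_removed` (logical) and
#'   `n_beats`.
#' @export
remove_ecg <- function(sig, reference, fs,
                       window_s = c(0.06, 0.08)) {
  if (length(sig) != length(reference))
    stop_param("signal and reference lengths differ")
  beats <- detect_beats(reference, fs)
  if (length(beats) < 3L) {
    warning("no detectable periodicity in reference; signal unchanged")
    return(structure(sig, ecg_removed = FALSE, n_beats = length(beats)))
  }
  pre <- round(window_s[1] * fs); post <- round(window_s[2] * fs)
  n <- length(sig)
  segs <- lapply(beats, function(b) {
    idx <- (b - pre):(b + post)
    if (idx[1] < 1L || idx[length(idx)] > n) NULL else sig[idx]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  beats <- beats[vapply(beats, function(b)
    b - pre >= 1L && b + post <= n, logical(1))]
  if (length(segs) < 3L) {
    warning("too few complete beat windows; signal unchanged")
    return(structure(sig, ecg_removed = FALSE, n_beats = length(segs)))
  }
  template <- Reduce(`+`, segs) / length(segs)
  # QRS energy is band-limited; low-passing the averaged template
  # strips the template-estimation noise without touching the beat
  # morphology
  lp <- signal::butter(4, min(150, 0.4 * fs) / (fs / 2), type = "low")
  template <- signal::filtfilt(lp, template)
  denom <- sum(template^2)
  out <- sig
  if (denom > 0) {
    for (k in seq_along(beats)) {
      idx <- (beats[k] - pre):(beats[k] + post)
      b_hat <- sum(out[idx] * template) / denom
      out[idx] <- out[idx] - b_hat * template
    }
  }
  structure(out, ecg_removed = TRUE, n_beats = length(beats))
}

#' Normalize a standing recording by bending reference contractions
#'
#' Each standing channel is divided by the RMS of the corresponding
#' channel in the same-side trunk-bending recording (left channels by
#' the bend-left recording, right channels by bend-right), yielding
#' dimensionless activity relative to a voluntary reference
#' contraction. Invariant to a common gain applied to all recordings.
#'
#' @param standing,bend_left,bend_right preprocessed
#'   [semg_recording()] objects with matching channel names.
#' @return a [semg_recording()] of dimensionless normalized series.
#' @export
bending_normalize <- function(standing, bend_left, bend_right) {
  stopifnot(inherits(standing, "semg_recording"),
            inherits(bend_left, "semg_recording"),
            inherits(bend_right, "semg_recording"))
  chans <- lapply(names(standing$channels), function(nm) {
    ref_rec <- if (grepl("left", nm)) bend_left else bend_right
    if (!nm %in% names(ref_rec$channels))
      stop_param("bending recording lacks channel ", nm)
    r <- rms(ref_rec$channels[[nm]])
    if (r == 0) stop_param("zero bending RMS on channel ", nm)
    standing$channels[[nm]] / r
  })
  names(chans) <- names(standing$channels)
  semg_recording(chans, fs = standing$fs, gain = 1,
                 posture = standing$posture)
}

#' Windowed burst metrics of one sEMG channel
#'
#' RMS over non-overlapping windows; a window is a burst when its RMS
#' exceeds `burst_k` times the median window RMS. Quantifies the
#' irregular-burst vs stationary distinction descriptively.
#'
#' @param sig preprocessed numeric channel.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s); default 0.25.
#' @param burst_k burst threshold in median-RMS units; default 3.
#' @return list: `burst_count`, `burst_fraction`, `rms` (whole
#'   channel), `window_rms` vector.
#' @export
burst_metrics <- function(sig, fs, window_s = 0.25, burst_k = 3) {
  win_n <- round(window_s * fs)
  if (win_n > length(sig)) stop_param("window longer than recording")
  n_win <- length(sig) %/% win_n
  wr <- vapply(seq_len(n_win), function(w)
    rms(sig[((w - 1) * win_n + 1):(w * win_n)]), numeric(1))
  med <- stats::median(wr)
  is_burst <- if (med > 0) wr > burst_k * med else wr > 0
  list(burst_count = sum(is_burst),
       burst_fraction = mean(is_burst),
       rms = rms(sig),
       window_rms = wr)
}

#' Left-right descriptive metrics of a recording
#'
#' @param rec preprocessed [semg_recording()].
#' @inheritParams burst_metrics
#' @return list of class `semg_metrics`: per-side RMS, their ratio
#'   `lr_rms_ratio` (left/right), and per-side burst metrics.
#' @export
semg_metrics <- function(rec, window_s = 0.25, burst_k = 3) {
  stopifnot(inherits(rec, "semg_recording"))
  bl <- burst_metrics(rec$channels$rec_left, rec$fs, window_s, burst_k)
  br <- burst_metrics(rec$channels$rec_right, rec$fs, window_s, burst_k)
  structure(list(
    left_rms = bl$rms, right_rms = br$rms,
    lr_rms_ratio = bl$rms / br$rms,
    left_bursts = bl, right_bursts = br), class = "semg_metrics")
}
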