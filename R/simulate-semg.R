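# synthetic paraspinal surface-EMG recordings

#' Construct an sEMG recording
#'
#' Four-channel container: a left/right recording pair placed over
#' the paraspinal muscles near the curve apex and a left/right
#' reference pair placed higher (T3-5 in the clinical protocol),
#' used for ECG removal.
#'
#' @param channels named list of equal-length numeric vectors; the
#'   canonical names are `rec_left`, `rec_right`, `ref_left`,
#'   `ref_right`.
#' @param fs sampling rate in Hz (2000 in the clinical protocol).
#' @param gain amplifier gain (dimensionless; 1000 in the protocol).
#' @param posture one of `"standing"`, `"bend_left"`, `"bend_right"`.
#' @return object of class `semg_recording`.
#' @export
semg_recording <- function(channels, fs = 2000, gain = 1000,
                           posture = c("standing", "bend_left", "bend_right")) {
  posture <- match.arg(posture)
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_param("channels must be a named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L || lens[1] == 0L)
    stop_param("all channels must have the same nonzero length")
  check_scalar(fs, "fs", lower = 0, closed_lower = FALSE)
  check_scalar(gain, "gain", lower = 0, closed_lower = FALSE)
  structure(list(channels = lapply(channels, as.numeric), fs = fs,
                 gain = gain, posture = posture),
            class = "semg_recording")
}

# biphasic QRS-like pulse, unit peak, ~80 ms wide
ecg_template_shape <- function(fs) {
  t <- seq(-0.04, 0.04, by = 1 / fs)
  w <- (1 - (t / 0.02)^2) * exp(-(t / 0.02)^2 / 2)  # Ricker wavelet
  w / max(abs(w))
}

#' Simulate a four-channel sEMG recording
#'
#' Background muscle activity is bandlimited Gaussian noise per
#' channel. A periodic QRS-like template (Ricker wavelet, ~75 bpm) is
#' mixed into every channel scaled by `ecg_amplitude`, emulating ECG
#' contamination; optional one-sided burst envelopes multiply the
#' recording channel of one side in randomly chosen windows,
#' emulating the irregular bursts seen in affected preadolescents
#' (stationary signal when `burst_spec` is `NULL`).
#'
#' @param duration_s recording length (s).
#' @param fs sampling rate (Hz); default 2000.
#' @param ecg_amplitude ECG peak amplitude relative to the unit-SD
#'   background (0 disables contamination).
#' @param burst_spec `NULL` for a stationary recording, or a list
#'   with elements `side` (`"left"`/`"right"`), `fraction` of windows
#'   carrying a burst, `gain` (amplitude multiplier) and optional
#'   `window_s` (default 0.25 s).
#' @param noise_sd background SD (signal units).
#' @param seed integer seed.
#' @return list with `recording` (a [semg_recording()]), the injected
#'   `ecg_beat_times` (s) and the injected `ecg_component` per channel
#'   (for template-energy accounting in tests).
#' @export
simulate_semg <- function(duration_s = 10, fs = 2000,
                          ecg_amplitude = 0, burst_spec = NULL,
                          noise_sd = 1, seed = 1L) {
  check_scalar(duration_s, "duration_s", lower = 0, closed_lower = FALSE)
  check_scalar(fs, "fs", lower = 100)
  check_scalar(ecg_amplitude, "ecg_amplitude", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  n <- round(duration_s * fs)
  ch_names <- c("rec_left", "rec_right", "ref_left", "ref_right")
  chans <- lapply(ch_names, function(nm) stats::rnorm(n, 0, noise_sd))
  names(chans) <- ch_names

  # one-sided multiplicative burst envelope on the recording channel
  if (!is.null(burst_spec)) {
    side <- match.arg(burst_spec$side, c("left", "right"))
    frac <- check_scalar(burst_spec$fraction, "burst fraction",
                         lower = 0, upper = 1)
    gain <- check_scalar(burst_spec$gain, "burst gain", lower = 1)
    win_n <- round((burst_spec$window_s %||% 0.25) * fs)
    n_win <- n %/% win_n
    burst_wins <- sort(sample(n_win, round(frac * n_win)))
    env <- rep(1, n)
    for (w in burst_wins)
      env[((w - 1) * win_n + 1):(w * win_n)] <- gain
    nm <- paste0("rec_", side)
    chans[[nm]] <- chans[[nm]] * env
  }

  # periodic ECG mixed into all channels (stronger on references,
  # which sit closer to the heart in the clinical montage)
  beat_times <- numeric(0)
  ecg_comp <- lapply(chans, function(x) numeric(n))
  if (ecg_amplitude > 0) {
    shape <- ecg_template_shape(fs)
    half <- (length(shape) - 1L) %/% 2L
    period <- 0.8  # ~75 bpm
    beat_times <- seq(0.4, duration_s - 0.2, by = period)
    ecg_track <- numeric(n)
    for (bt in beat_times) {
      c0 <- round(bt * fs)
      idx <- (c0 - half):(c0 + half) + 1L
      keep <- idx >= 1L & idx <= n
      ecg_track[idx[keep]] <- ecg_track[idx[keep]] + shape[keep]
    }
    mix <- c(rec_left = 1, rec_right = 1, ref_left = 1.5, ref_right = 1.5)
    for (nm in ch_names) {
      ecg_comp[[nm]] <- ecg_amplitude * mix[[nm]] * ecg_track
      chans[[nm]] <- chans[[nm]] + ecg_comp[[nm]]
    }
  }
  list(recording = semg_recording(chans, fs = fs),
       ecg_beat_times = beat_times,
       ecg_component = ecg_comp)
}
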