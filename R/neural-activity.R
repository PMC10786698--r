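# bilateral spinal calcium-activity quantification

#' Baseline specifications for dF extraction
#'
#' `baseline_manual(value)` uses a fixed, user-chosen F0.
#' `baseline_rolling_percentile(p, window_s)` estimates F0(t) as the
#' `p` quantile of F over a centered rolling window — robust to slow
#' drift; the default (10th percentile over 20 s) tracks the
#' between-event floor of a sparse calcium recording.
#'
#' @param value fixed baseline F0 (fluorescence units).
#' @param p percentile in (0, 1); default 0.10.
#' @param window_s rolling window length (s); default 20.
#' @return a baseline specification object for [compute_dff()].
#' @export
baseline_manual <- function(value) {
  check_scalar(value, "value")
  structure(list(method = "manual", value = value),
            class = "dff_baseline")
}

#' @rdname baseline_manual
#' @export
baseline_rolling_percentile <- function(p = 0.10, window_s = 20) {
  check_scalar(p, "p", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_scalar(window_s, "window_s", lower = 0, closed_lower = FALSE)
  structure(list(method = "rolling_percentile", p = p,
                 window_s = window_s),
            class = "dff_baseline")
}

#' Baseline-subtracted fluorescence, dF = F(t) - F0
#'
#' @param trace numeric fluorescence series F(t).
#' @param baseline a [baseline_manual()] or
#'   [baseline_rolling_percentile()] specification.
#' @param fps frames/s; required for the rolling baseline.
#' @return numeric dF series of the same length.
#' @export
compute_dff <- function(trace, baseline, fps = NULL) {
  if (length(trace) == 0L) stop_param("trace is empty")
  if (!all(is.finite(trace))) stop_param("trace has non-finite values")
  if (!inherits(baseline, "dff_baseline"))
    stop_param("baseline must be a dff_baseline specification")
  if (baseline$method == "manual")
    return(trace - baseline$value)
  check_scalar(fps, "fps", lower = 0, closed_lower = FALSE)
  width <- round(baseline$window_s * fps)
  if (width > length(trace))
    stop_param("rolling window (", width, " frames) longer than trace (",
               length(trace), " frames)")
  f0 <- zoo::rollapply(zoo::zoo(trace), width = width,
                       FUN = stats::quantile, probs = baseline$p,
                       names = FALSE, partial = TRUE, align = "center")
  trace - as.numeric(f0)
}

#' Relative intensity: dF as a percentage of its mean
#'
#' @param dff numeric dF series with nonzero mean.
#' @return series `100 * dff / mean(dff)`; its mean is 100 by
#'   construction.
#' @export
relative_intensity <- function(dff) {
  if (length(dff) == 0L) stop_param("dff is empty")
  m <- mean(dff)
  if (!is.finite(m) || abs(m) < .Machine$double.eps * 100 * max(1, max(abs(dff))))
    stop_param("mean(dff) is zero; relative intensity undefined")
  100 * dff / m
}

# robust noise SD of a sparse-event trace: MAD of first differences
# over sqrt(2). Differencing whitens the slow calcium transients, so
# the estimate is far less inflated by the events themselves than the
# MAD of the raw series.
robust_noise_sd <- function(x) {
  if (length(x) < 2L) return(0)
  stats::mad(diff(x), constant = 1.4826) / sqrt(2)
}

# topographic prominence of a peak at index i: height above the
# deepest trough separating it from higher ground on each side
peak_prominence <- function(x, i) {
  n <- length(x)
  min_l <- x[i]; j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) { min_l <- min(min_l, x[j]); j <- j - 1L }
  min_r <- x[i]; j <- i + 1L
  while (j <= n && x[j] <= x[i]) { min_r <- min(min_r, x[j]); j <- j + 1L }
  # boundary counts as higher ground only if never exceeded
  x[i] - max(min_l, min_r)
}

# single-series event detection. Candidate events are supra-threshold
# excursions of dff above threshold_k * robust SD; within each
# excursion, local maxima must also have topographic prominence above
# the threshold (rejecting noise re-crossings on a transient's slow
# decay while keeping genuine consecutive same-side events). Onsets
# are the upward threshold crossing (first event of an excursion) or
# the preceding trough (subsequent ones). The refractory rule keeps
# the larger of two events whose onsets are nearer than
# min_interval_s.
detect_peaks_series <- function(dff, fps, threshold_k, min_interval_s,
                                min_width = 2L) {
  if (!all(is.finite(dff))) stop_param("dff has non-finite values")
  # center on the median: a percentile baseline leaves dff with a
  # positive offset, and the threshold must sit k robust SDs above
  # the noise center, not above zero
  dff <- dff - stats::median(dff)
  sigma <- robust_noise_sd(dff)
  thr <- threshold_k * sigma
  # hysteresis: an excursion is a run above thr/2 lasting at least
  # min_width samples and reaching thr at least once, so a borderline
  # transient is not fragmented by noise while single-sample noise
  # spikes (no realistic transient is that short) are dropped
  above_hi <- dff > thr
  above_lo <- dff > thr / 2
  r <- rle(above_lo)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width &
    mapply(function(s, e) any(above_hi[s:e]), run_ends - r$lengths + 1L,
           run_ends)
  run_starts <- run_starts[keep]; run_ends <- run_ends[keep]
  onset_idx <- integer(0); amp <- numeric(0)
  for (k in seq_along(run_starts)) {
    s <- run_starts[k]; e <- run_ends[k]
    seg <- dff[s:e]
    pk <- if (e - s < 2L) s - 1L + which.max(seg)
          else s - 1L + unique(c(local_maxima(c(-Inf, seg, -Inf)) - 1L))
    pk <- pk[dff[pk] > thr]
    pk <- pk[vapply(pk, function(i) peak_prominence(dff, i) > thr,
                    logical(1))]
    if (!length(pk)) next
    pk <- sort(pk)
    on <- s - 1L + which(above_hi[s:e])[1]  # first hi crossing
    for (m in seq_along(pk)) {
      if (m > 1L) {
        trough <- pk[m - 1L] + which.min(dff[pk[m - 1L]:pk[m]]) - 1L
        on <- trough
      }
      onset_idx <- c(onset_idx, on)
      amp <- c(amp, dff[pk[m]])
    }
  }
  if (!length(onset_idx))
    return(list(idx = integer(0), amp = numeric(0)))
  ord <- order(amp, decreasing = TRUE)
  min_gap <- min_interval_s * fps
  kept <- integer(0)
  for (j in ord)
    if (!length(kept) ||
        all(abs(onset_idx[kept] - onset_idx[j]) >= min_gap))
      kept <- c(kept, j)
  kept <- kept[order(onset_idx[kept])]
  list(idx = onset_idx[kept], amp = amp[kept])
}

#' Detect activity events in bilateral dF traces
#'
#' Events are local maxima of the per-side dF signal exceeding
#' `threshold_k` times a robust noise SD (median absolute deviation)
#' above the signal's median, separated by at least `min_interval_s`
#' (refractory rule: of two nearer peaks only the larger survives);
#' amplitudes are reported relative to the median. Left and right events with
#' onsets within `coincidence_window_s` of each other are merged into
#' a single `bilateral` event (amplitude = sum, onset = mean).
#'
#' @param dff per-side dF input: either a named list
#'   `list(left =, right =)` of numeric series, or a single numeric
#'   series (treated as `side` below).
#' @param fps frames/s.
#' @param threshold_k detection threshold in robust-SD units
#'   (default 3).
#' @param min_interval_s refractory interval (s); must be at least
#'   one frame.
#' @param coincidence_window_s left/right merge window (s),
#'   default 0.2.
#' @param side side label used when `dff` is a bare series.
#' @return an [event_train()].
#' @export
detect_events <- function(dff, fps, threshold_k = 3,
                          min_interval_s = 0.5,
                          coincidence_window_s = 0.2,
                          side = "left") {
  check_scalar(threshold_k, "threshold_k", lower = 0, closed_lower = FALSE)
  check_scalar(fps, "fps", lower = 0, closed_lower = FALSE)
  if (min_interval_s < 1 / fps)
    stop_param("min_interval_s must be at least one frame (1/fps)")
  if (is.numeric(dff)) {
    pk <- detect_peaks_series(dff, fps, threshold_k, min_interval_s)
    return(event_train((pk$idx - 1L) / fps, rep(side, length(pk$idx)),
                       pk$amp))
  }
  stopifnot(is.list(dff), all(c("left", "right") %in% names(dff)))
  trains <- lapply(c("left", "right"), function(s) {
    pk <- detect_peaks_series(dff[[s]], fps, threshold_k, min_interval_s)
    tibble::tibble(onset_time = (pk$idx - 1L) / fps,
                   side = rep(s, length(pk$idx)), amplitude = pk$amp)
  })
  ev <- do.call(rbind, trains)
  ev <- ev[order(ev$onset_time), ]
  merge_coincident(ev, coincidence_window_s)
}

# merge opposite-side events closer than the coincidence window
merge_coincident <- function(ev, window_s) {
  n <- nrow(ev)
  if (n == 0L) return(event_train())
  onset <- ev$onset_time; side <- ev$side; amp <- ev$amplitude
  keep_onset <- numeric(0); keep_side <- character(0); keep_amp <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (i < n && side[i] != side[i + 1L] &&
        (onset[i + 1L] - onset[i]) <= window_s) {
      keep_onset <- c(keep_onset, mean(onset[i:(i + 1L)]))
      keep_side <- c(keep_side, "bilateral")
      keep_amp <- c(keep_amp, amp[i] + amp[i + 1L])
      i <- i + 2L
    } else {
      keep_onset <- c(keep_onset, onset[i])
      keep_side <- c(keep_side, side[i])
      keep_amp <- c(keep_amp, amp[i])
      i <- i + 1L
    }
  }
  event_train(keep_onset, keep_side, keep_amp)
}

#' Left-right alternation index
#'
#' The number of consecutive event pairs occurring on opposite sides
#' of the spinal cord, divided by the total number of events minus 1.
#' A value of 1 means perfect left-right alternation; pairs involving
#' a merged `bilateral` event count as not-opposite (synchronous
#' bilateral activation is the discoordination phenotype).
#'
#' @param events an [event_train()] (or data frame with `onset_time`
#'   and `side`) holding at least 2 events.
#' @return scalar in `[0, 1]`.
#' @export
alternation_index <- function(events) {
  n <- nrow(events)
  if (is.null(n) || n < 2L)
    stop_param("alternation index undefined for fewer than 2 events")
  side <- events$side[order(events$onset_time)]
  a <- side[-n]; b <- side[-1L]
  opposite <- (a == "left" & b == "right") | (a == "right" & b == "left")
  sum(opposite) / (n - 1L)
}

#' Event frequency on one side
#'
#' Count of events on the requested side divided by the recording
#' duration, in Hz. The published quantification uses the left side.
#'
#' @param events an [event_train()].
#' @param side `"left"`, `"right"` or `"bilateral"`.
#' @param duration_s recording duration (s).
#' @return frequency in Hz.
#' @export
event_frequency <- function(events, side = "left", duration_s) {
  check_scalar(duration_s, "duration_s", lower = 0, closed_lower = FALSE)
  sum(events$side == side) / duration_s
}

#' Total signal: time-integral of dF
#'
#' Trapezoidal integral of the dF series over the recording, in
#' dF-units times seconds; operationalizes "total signal" per ROI.
#'
#' @param dff numeric dF series.
#' @param fps frames/s.
#' @return scalar integral.
#' @export
total_signal <- function(dff, fps) {
  if (!all(is.finite(dff))) stop_param("dff has non-finite values")
  check_scalar(fps, "fps", lower = 0, closed_lower = FALSE)
  if (length(dff) < 2L) return(0)
  pracma::trapz((seq_along(dff) - 1L) / fps, dff)
}

# per-side summed dF of a bilateral trace set
per_side_dff <- function(traces, baseline, fps) {
  sides <- c("left", "right")
  out <- lapply(sides, function(s) {
    d <- traces$data[traces$data$side == s, ]
    ids <- unique(d$roi_id)
    mats <- vapply(ids, function(id)
      compute_dff(d$value[d$roi_id == id], baseline, fps = fps),
      numeric(sum(d$roi_id == ids[1])))
    rowSums(as.matrix(mats))
  })
  names(out) <- sides
  out
}

#' Summarize bilateral activity of one recording
#'
#' Full quantification pipeline: per-ROI dF extraction, per-side
#' summation ("quantified intensities of total left- and right-side
#' neural activities"), event detection with coincidence merging,
#' then the alternation index, left-side frequency, event count and
#' per-ROI total signal.
#'
#' @param traces a [bilateral_traces()] object.
#' @param baseline baseline specification; default
#'   [baseline_rolling_percentile()].
#' @param threshold_k,min_interval_s,coincidence_window_s detector
#'   settings, see [detect_events()].
#' @return list of class `activity_summary` with fields
#'   `alternation_index`, `left_frequency_hz`, `n_events`, `events`,
#'   `total_signal` (named per-ROI vector).
#' @export
activity_summary <- function(traces,
                             baseline = baseline_rolling_percentile(),
                             threshold_k = 3, min_interval_s = 0.5,
                             coincidence_window_s = 0.2) {
  stopifnot(inherits(traces, "bilateral_traces"))
  dff_sides <- per_side_dff(traces, baseline, traces$fps)
  events <- detect_events(dff_sides, fps = traces$fps,
                          threshold_k = threshold_k,
                          min_interval_s = min_interval_s,
                          coincidence_window_s = coincidence_window_s)
  n_ev <- nrow(events)
  ai <- if (n_ev >= 2L) alternation_index(events) else NA_real_
  ids <- unique(traces$data$roi_id)
  tot <- vapply(ids, function(id) {
    tr <- traces$data$value[traces$data$roi_id == id]
    total_signal(compute_dff(tr, baseline, fps = traces$fps), traces$fps)
  }, numeric(1))
  structure(list(
    alternation_index = ai,
    left_frequency_hz = event_frequency(events, "left", traces$duration),
    n_events = n_ev,
    events = events,
    total_signal = tot), class = "activity_summary")
}
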