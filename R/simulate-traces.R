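# synthetic bilateral calcium recordings with ground-truth events

#' Construct a bilateral trace set
#'
#' Container for per-ROI fluorescence time series labeled left/right.
#' All ROIs must share the sampling rate and length.
#'
#' @param data tibble with columns `time_s`, `roi_id`, `side`
#'   (`"left"`/`"right"`), `value` (fluorescence, arbitrary units).
#' @param fps sampling rate (frames/s).
#' @param duration recording duration (s).
#' @return object of class `bilateral_traces`.
#' @export
bilateral_traces <- function(data, fps, duration) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "roi_id", "side", "value") %in% names(data)))
  if (!all(data$side %in% c("left", "right")))
    stop_param("side labels must be 'left' or 'right'")
  lens <- table(data$roi_id)
  if (length(unique(as.integer(lens))) > 1L)
    stop_param("all ROIs must have the same number of frames")
  check_scalar(fps, "fps", lower = 0, closed_lower = FALSE)
  check_scalar(duration, "duration", lower = 0, closed_lower = FALSE)
  structure(list(data = tibble::as_tibble(data), fps = fps,
                 duration = duration),
            class = "bilateral_traces")
}

#' Construct an event train
#'
#' Time-ordered train of detected (or ground-truth) activity events.
#'
#' @param onset_time event onset times (s).
#' @param side one of `"left"`, `"right"`, `"bilateral"` per event.
#' @param amplitude peak amplitudes (dF units).
#' @param roi_id optional ROI label per event.
#' @return a tibble of class `event_train`, sorted by onset time.
#' @export
event_train <- function(onset_time = numeric(), side = character(),
                        amplitude = numeric(),
                        roi_id = rep(NA_character_, length(onset_time))) {
  if (!all(side %in% c("left", "right", "bilateral")))
    stop_param("side must be left, right or bilateral")
  out <- tibble::tibble(onset_time = as.numeric(onset_time),
                        side = as.character(side),
                        amplitude = as.numeric(amplitude),
                        roi_id = as.character(roi_id))
  out <- out[order(out$onset_time), ]
  class(out) <- c("event_train", class(tibble::tibble()))
  out
}

# draw event times (refractory renewal) and sides (Bernoulli switching)
draw_event_train <- function(event_rate, min_gap, switch_prob, duration,
                             amplitude_mean, amplitude_cv) {
  if (event_rate <= 0) return(event_train())
  # gaps = min_gap + exponential tail; mean gap = 1/event_rate
  tail_rate <- 1 / (1 / event_rate - min_gap)
  n_max <- max(10, ceiling(event_rate * duration * 3 + 20))
  times <- cumsum(min_gap + stats::rexp(n_max, rate = tail_rate))
  times <- times[times < duration]
  n <- length(times)
  if (n == 0L) return(event_train())
  sides <- character(n)
  sides[1] <- sample(c("left", "right"), 1L)
  if (n > 1L) {
    flips <- stats::runif(n - 1L) < switch_prob
    for (i in 2:n)
      sides[i] <- if (flips[i - 1L]) setdiff(c("left", "right"), sides[i - 1L])
                  else sides[i - 1L]
  }
  if (amplitude_cv > 0) {
    shape <- 1 / amplitude_cv^2
    amps <- stats::rgamma(n, shape = shape,
                          rate = shape / amplitude_mean)
  } else {
    amps <- rep(amplitude_mean, n)
  }
  event_train(times, sides, amps)
}

#' Simulate a bilateral spinal calcium recording
#'
#' Generates per-ROI GCaMP-style fluorescence traces from a
#' ground-truth event train. Events arise as a Poisson renewal process
#' over the whole fish; each event's side follows a Bernoulli
#' switching process (probability `switch_prob` of changing side), so
#' the expected alternation index of the ground truth is
#' `switch_prob`. Each trace is
#' `baseline + drift * t + sum of event kernels + Gaussian noise`,
#' with events rendered on every ROI of their side using the
#' unit-peak double-exponential [calcium_kernel()].
#'
#' @param params a [cpg_sim_params()] object.
#' @return list with elements `traces` (a [bilateral_traces()] object)
#'   and `events` (the ground-truth [event_train()]).
#' @examples
#' sim <- simulate_bilateral_traces(cpg_sim_params(seed = 7))
#' head(sim$traces$data)
#' head(sim$events)
#' @export
simulate_bilateral_traces <- function(params) {
  if (!inherits(params, "cpg_sim_params"))
    stop_param("params must be a cpg_sim_params object")
  p <- params
  set.seed(p$seed)
  events <- draw_event_train(p$event_rate, p$min_gap, p$switch_prob,
                             p$duration, p$amplitude_mean, p$amplitude_cv)
  n_frames <- round(p$fps * p$duration)
  t_grid <- (seq_len(n_frames) - 1L) / p$fps
  # kernels are rendered on a local support window (10 decay
  # constants; < 5e-5 of the peak beyond it) so rendering scales with
  # the event count, not events x frames
  support <- ceiling(10 * p$kernel_tau_decay * p$fps)
  clean_side <- function(side) {
    sig <- p$baseline_level + p$baseline_drift_slope * t_grid
    ev <- events[events$side == side, ]
    for (i in seq_len(nrow(ev))) {
      i0 <- max(1L, floor(ev$onset_time[i] * p$fps) + 1L)
      i1 <- min(n_frames, i0 + support)
      idx <- i0:i1
      sig[idx] <- sig[idx] + ev$amplitude[i] *
        calcium_kernel(t_grid[idx] - ev$onset_time[i],
                       p$kernel_tau_rise, p$kernel_tau_decay)
    }
    sig
  }
  base_left <- clean_side("left")
  base_right <- clean_side("right")
  rois <- list()
  for (s in c("left", "right")) {
    base <- if (s == "left") base_left else base_right
    for (k in seq_len(p$n_rois_per_side)) {
      noise <- if (p$noise_sd > 0) stats::rnorm(n_frames, 0, p$noise_sd)
               else numeric(n_frames)
      rois[[length(rois) + 1L]] <- tibble::tibble(
        time_s = t_grid,
        roi_id = sprintf("%s_%02d", s, k),
        side = s,
        value = base + noise)
    }
  }
  traces <- bilateral_traces(do.call(rbind, rois), fps = p$fps,
                             duration = p$duration)
  list(traces = traces, events = events)
}
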