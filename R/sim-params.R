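# parameter objects for the synthetic-data generators

#' Parameters for the bilateral calcium-trace generator
#'
#' Bundles and validates every knob of [simulate_bilateral_traces()].
#' Event laterality follows a Bernoulli switching process: after each
#' event the next one lands on the opposite side with probability
#' `switch_prob`, so the expected left-right alternation index of the
#' ground-truth train equals `switch_prob` — an analytic recovery
#' target for the detection pipeline.
#'
#' @param event_rate whole-fish event rate (events/s). Events form a
#'   refractory renewal process: inter-event gaps are `min_gap` plus
#'   an exponential tail, with the tail rate set so the mean gap is
#'   `1/event_rate`. A CPG is quasi-rhythmic, not memoryless, so a
#'   strictly Poisson train (coincident left/right events) would be
#'   unrealistic; `min_gap = 0` recovers the pure Poisson case.
#' @param min_gap minimum inter-event interval (s); default 0.75,
#'   and must stay below `1/event_rate`.
#' @param switch_prob probability in `[0, 1]` that the next event
#'   occurs on the side opposite to the previous one.
#' @param kernel_tau_rise,kernel_tau_decay calcium transient rise and
#'   decay time constants (s).
#' @param amplitude_mean,amplitude_cv mean and coefficient of
#'   variation of event peak amplitudes (fluorescence units).
#' @param baseline_level baseline fluorescence F0 (arbitrary units).
#' @param baseline_drift_slope linear baseline drift (units/s).
#' @param noise_sd additive Gaussian noise SD (units).
#' @param fps sampling rate (frames/s); recordings here use 10 fps.
#' @param duration recording length (s); default one minute.
#' @param n_rois_per_side number of ROIs per hemicord.
#' @param seed integer seed; equal seeds give bit-identical output.
#' @return an object of class `cpg_sim_params`.
#' @export
cpg_sim_params <- function(event_rate = 0.2,
                           min_gap = 0.75,
                           switch_prob = 0.9,
                           kernel_tau_rise = 0.1,
                           kernel_tau_decay = 0.8,
                           amplitude_mean = 10,
                           amplitude_cv = 0.2,
                           baseline_level = 100,
                           baseline_drift_slope = 0,
                           noise_sd = 0.5,
                           fps = 10,
                           duration = 60,
                           n_rois_per_side = 1,
                           seed = 1L) {
  check_scalar(event_rate, "event_rate", lower = 0)
  check_scalar(min_gap, "min_gap", lower = 0)
  if (event_rate > 0 && min_gap >= 1 / event_rate)
    stop_param("min_gap must be below the mean gap 1/event_rate")
  check_scalar(switch_prob, "switch_prob", lower = 0, upper = 1)
  check_scalar(kernel_tau_rise, "kernel_tau_rise", lower = 0, closed_lower = FALSE)
  check_scalar(kernel_tau_decay, "kernel_tau_decay", lower = 0, closed_lower = FALSE)
  if (kernel_tau_decay <= kernel_tau_rise)
    stop_param("kernel_tau_decay must exceed kernel_tau_rise")
  check_scalar(amplitude_mean, "amplitude_mean", lower = 0)
  check_scalar(amplitude_cv, "amplitude_cv", lower = 0)
  check_scalar(baseline_level, "baseline_level")
  check_scalar(baseline_drift_slope, "baseline_drift_slope")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(fps, "fps", lower = 0, closed_lower = FALSE)
  check_scalar(duration, "duration", lower = 0, closed_lower = FALSE)
  n_rois_per_side <- check_count(n_rois_per_side, "n_rois_per_side")
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(event_rate = event_rate, min_gap = min_gap,
         switch_prob = switch_prob,
         kernel_tau_rise = kernel_tau_rise,
         kernel_tau_decay = kernel_tau_decay,
         amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
         baseline_level = baseline_level,
         baseline_drift_slope = baseline_drift_slope,
         noise_sd = noise_sd, fps = fps, duration = duration,
         n_rois_per_side = n_rois_per_side, seed = seed),
    class = "cpg_sim_params")
}

#' Parameters for the fish-midline generator
#'
#' @param theta_deg target curvature angle in degrees, in `[0, 180)`.
#' @param n_points number of midline points (head to tail), `>= 3`.
#' @param body_length arc length of the body (mm).
#' @param noise_sd isotropic Gaussian coordinate noise SD (mm).
#' @param seed integer seed.
#' @return an object of class `midline_sim_params`.
#' @export
midline_sim_params <- function(theta_deg,
                               n_points = 51,
                               body_length = 4,
                               noise_sd = 0,
                               seed = 1L) {
  check_scalar(theta_deg, "theta_deg", lower = 0, upper = 180,
               closed_upper = FALSE)
  n_points <- check_count(n_points, "n_points", min = 3L)
  check_scalar(body_length, "body_length", lower = 0, closed_lower = FALSE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(theta_deg = theta_deg, n_points = n_points,
         body_length = body_length, noise_sd = noise_sd, seed = seed),
    class = "midline_sim_params")
}

#' Parameters for the case-control cohort generator
#'
#' @param n_case_alleles,n_control_alleles total allele counts
#'   (2 per diploid subject).
#' @param case_allele_freq,control_allele_freq variant allele
#'   frequencies as proportions in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_case_alleles,
                              n_control_alleles,
                              case_allele_freq,
                              control_allele_freq,
                              seed = 1L) {
  n_case_alleles <- check_count(n_case_alleles, "n_case_alleles")
  n_control_alleles <- check_count(n_control_alleles, "n_control_alleles")
  check_scalar(case_allele_freq, "case_allele_freq", lower = 0, upper = 1)
  check_scalar(control_allele_freq, "control_allele_freq", lower = 0, upper = 1)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(n_case_alleles = n_case_alleles,
         n_control_alleles = n_control_alleles,
         case_allele_freq = case_allele_freq,
         control_allele_freq = control_allele_freq, seed = seed),
    class = "cohort_sim_params")
}
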