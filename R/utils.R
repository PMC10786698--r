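# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(
    class = c("scoliquant_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a single finite number")
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_param(name, " = ", format(x), " is outside ",
               if (closed_lower) "[" else "(", lower, ", ", upper,
               if (closed_upper) "]" else ")")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name, lower = min)
  if (x != round(x)) stop_param(name, " must be an integer count")
  invisible(as.integer(x))
}

#' Double-exponential calcium transient kernel
#'
#' Unit-peak transient shape `exp(-t/tau_decay) - exp(-t/tau_rise)`
#' (zero for `t < 0`), normalized so its maximum is 1. This is the
#' minimal rise/decay model of a single-event GCaMP fluorescence
#' transient used by the trace generator.
#'
#' @param t numeric vector of times (s), relative to event onset.
#' @param tau_rise,tau_decay rise and decay time constants (s);
#'   `tau_decay > tau_rise > 0`.
#' @return numeric vector of kernel values in `[0, 1]`.
#' @seealso [calcium_kernel_area()] for its closed-form integral.
#' @export
calcium_kernel <- function(t, tau_rise, tau_decay) {
  check_scalar(tau_rise, "tau_rise", lower = 0, closed_lower = FALSE)
  check_scalar(tau_decay, "tau_decay", lower = 0, closed_lower = FALSE)
  if (tau_decay <= tau_rise) stop_param("tau_decay must exceed tau_rise")
  raw <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  raw / calcium_kernel_peak(tau_rise, tau_decay)
}

calcium_kernel_peak <- function(tau_rise, tau_decay) {
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
}

#' Closed-form area of the unit-peak calcium kernel
#'
#' Integral over `[0, Inf)` of [calcium_kernel()]:
#' `(tau_decay - tau_rise) / peak`, the oracle used to check the
#' trapezoidal `total_signal` integral.
#'
#' @inheritParams calcium_kernel
#' @return scalar area (s, since the kernel is dimensionless).
#' @export
calcium_kernel_area <- function(tau_rise, tau_decay) {
  (tau_decay - tau_rise) / calcium_kernel_peak(tau_rise, tau_decay)
}

# indices of strict local maxima (plateaus take the first index)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

rms <- function(x) sqrt(mean(x^2))
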