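# midline, cohort and uptake-plate generators

#' Simulate a fish midline of known curvature
#'
#' Builds the body axis as a circular arc of central angle
#' `2 * theta_deg`, so that the curvature statistic of
#' [theta_angle()] — vertex at maximal chord deviation, 180 degrees
#' minus the vertex interior angle — equals `theta_deg` in closed
#' form. `theta_deg = 0` gives a straight body. Optional isotropic
#' Gaussian noise is added to both coordinates.
#'
#' @param params a [midline_sim_params()] object.
#' @return a [body_axis()] object, points ordered head to tail.
#' @examples
#' ax <- simulate_midline(midline_sim_params(theta_deg = 45))
#' theta_angle(ax)
#' @export
simulate_midline <- function(params) {
  if (!inherits(params, "midline_sim_params"))
    stop_param("params must be a midline_sim_params object")
  p <- params
  set.seed(p$seed)
  if (p$theta_deg == 0) {
    s <- seq(0, p$body_length, length.out = p$n_points)
    x <- s; y <- rep(0, p$n_points)
  } else {
    half <- p$theta_deg * pi / 180          # half the central angle
    radius <- p$body_length / (2 * half)    # arc length = R * 2 * half
    phi <- seq(-half, half, length.out = p$n_points)
    x <- radius * sin(phi)
    y <- radius * cos(phi)
  }
  if (p$noise_sd > 0) {
    x <- x + stats::rnorm(p$n_points, 0, p$noise_sd)
    y <- y + stats::rnorm(p$n_points, 0, p$noise_sd)
  }
  body_axis(x, y)
}

#' Simulate a case-control cohort allele table
#'
#' Variant-allele counts are binomial draws at the stated
#' frequencies: `Binom(n_case_alleles, case_allele_freq)` for cases
#' and likewise for controls.
#'
#' @param params a [cohort_sim_params()] object.
#' @return a [cohort_table()] with one row per group
#'   (`"case"`, `"control"`).
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_sim_params"))
    stop_param("params must be a cohort_sim_params object")
  p <- params
  set.seed(p$seed)
  cohort_table(
    group = c("case", "control"),
    variant_alleles = c(
      stats::rbinom(1L, p$n_case_alleles, p$case_allele_freq),
      stats::rbinom(1L, p$n_control_alleles, p$control_allele_freq)),
    total_alleles = c(p$n_case_alleles, p$n_control_alleles))
}

#' Simulate a glycine-uptake assay plate
#'
#' Per-well uptake quantity is `rate * time * protein * (1 + e)` with
#' `e ~ N(0, noise_cv)`, so [uptake_rate()] recovers the generating
#' rates exactly when `noise_cv = 0`.
#'
#' @param true_rates_by_genotype named numeric vector of true uptake
#'   rates (nmol/min/mg protein), e.g. `c(WT = 1, Y206F = 0.4)`.
#' @param protein_mg protein mass per well (mg).
#' @param time_min incubation time (min).
#' @param n_replicates wells per genotype.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @return an [uptake_plate()] tibble with one row per well.
#' @export
simulate_uptake_plate <- function(true_rates_by_genotype,
                                  protein_mg = 0.5,
                                  time_min = 10,
                                  n_replicates = 4,
                                  noise_cv = 0.05,
                                  seed = 1L) {
  if (is.null(names(true_rates_by_genotype)) ||
      any(!nzchar(names(true_rates_by_genotype))))
    stop_param("true_rates_by_genotype must be a named vector")
  if (any(true_rates_by_genotype < 0))
    stop_param("uptake rates must be nonnegative")
  check_scalar(protein_mg, "protein_mg", lower = 0, closed_lower = FALSE)
  check_scalar(time_min, "time_min", lower = 0, closed_lower = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_scalar(noise_cv, "noise_cv", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  genos <- rep(names(true_rates_by_genotype), each = n_replicates)
  rates <- rep(unname(true_rates_by_genotype), each = n_replicates)
  n <- length(genos)
  e <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else numeric(n)
  uptake_plate(
    well = sprintf("W%02d", seq_len(n)),
    genotype = genos,
    nmol = pmax(0, rates * time_min * protein_mg * (1 + e)),
    time_min = rep(time_min, n),
    protein_mg = rep(protein_mg, n),
    replicate = rep(seq_len(n_replicates),
                    times = length(true_rates_by_genotype)))
}
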