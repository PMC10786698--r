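# axial-curvature morphometrics: theta angle, penetrance, dose-response

#' Construct a body axis
#'
#' Ordered 2D midline of one fish, head first.
#'
#' @param x,y coordinates (mm or pixels), head to tail.
#' @param fish_id,genotype,treatment,age_dpf optional metadata.
#' @return object of class `body_axis`.
#' @export
body_axis <- function(x, y, fish_id = NA_character_,
                      genotype = NA_character_,
                      treatment = NA_character_, age_dpf = NA_real_) {
  if (length(x) != length(y)) stop_param("x and y lengths differ")
  if (length(x) < 3L) stop_param("a body axis needs at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_param("coordinates must be finite")
  dup <- diff(x) == 0 & diff(y) == 0
  if (any(dup)) { x <- x[c(TRUE, !dup)]; y <- y[c(TRUE, !dup)] }
  if (length(x) < 3L) stop_param("fewer than 3 distinct points")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 fish_id = fish_id, genotype = genotype,
                 treatment = treatment, age_dpf = age_dpf),
            class = "body_axis")
}

# centered moving average that leaves the endpoints in place
smooth_midline <- function(x, window) {
  if (window <= 1L || length(x) < window + 2L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  bad <- is.na(sm)
  sm[bad] <- x[bad]
  sm[1] <- x[1]; sm[length(x)] <- x[length(x)]
  sm
}

#' Body-curvature theta angle
#'
#' Scalar severity of axial curvature. The vertex is the midline
#' point of maximal perpendicular distance from the head-tail chord;
#' theta is 180 degrees minus the interior angle at the vertex
#' between the vertex-to-head and vertex-to-tail vectors. A straight
#' body gives 0; for a circular arc of central angle `2*theta` the
#' statistic equals `theta` exactly (inscribed-angle geometry), which
#' is the closed-form oracle used in the tests. Invariant under
#' rotation, translation, reflection, uniform scaling and reversal
#' of the point order.
#'
#' @param axis a [body_axis()] object.
#' @param smooth_window moving-average window (points) applied before
#'   vertex selection; default 3, which stabilizes the vertex under
#'   pixel noise. Endpoints are never smoothed.
#' @return angle in degrees, in `[0, 180)`.
#' @export
theta_angle <- function(axis, smooth_window = 3) {
  stopifnot(inherits(axis, "body_axis"))
  x <- smooth_midline(axis$x, smooth_window)
  y <- smooth_midline(axis$y, smooth_window)
  n <- length(x)
  head_pt <- c(x[1], y[1]); tail_pt <- c(x[n], y[n])
  chord <- tail_pt - head_pt
  chord_len <- sqrt(sum(chord^2))
  span <- max(max(x) - min(x), max(y) - min(y))
  if (span == 0) stop_param("degenerate axis: all points coincident")
  if (chord_len == 0) stop_param("degenerate axis: head equals tail")
  # perpendicular distance of each interior point to the chord
  dx <- x - head_pt[1]; dy <- y - head_pt[2]
  dist <- abs(dx * chord[2] - dy * chord[1]) / chord_len
  dist[c(1, n)] <- 0
  if (max(dist) <= 1e-9 * span) return(0)  # collinear
  v <- which.max(dist)
  a <- c(x[1] - x[v], y[1] - y[v])
  b <- c(x[n] - x[v], y[n] - y[v])
  interior <- acos(pmin(1, pmax(-1,
    sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  180 - interior * 180 / pi
}

#' Classify a fish as curved
#'
#' Curvature phenotype call: theta at or above the threshold
#' (boundary inclusive, matching the >= 10 degree convention).
#'
#' @param theta_deg curvature angle(s) in degrees.
#' @param threshold_deg phenotype threshold; default 10.
#' @return logical vector.
#' @export
classify_curved <- function(theta_deg, threshold_deg = 10) {
  if (!all(is.finite(theta_deg))) stop_param("theta must be finite")
  theta_deg >= threshold_deg
}

#' Penetrance of the curvature phenotype
#'
#' @param thetas numeric vector of per-fish theta angles (degrees).
#' @param threshold_deg phenotype threshold; default 10.
#' @return list of class `penetrance_summary`: `n_total`, `n_curved`,
#'   `penetrance_pct` (unrounded percentage), `thetas` (severity
#'   distribution).
#' @export
penetrance <- function(thetas, threshold_deg = 10) {
  if (length(thetas) == 0L) stop_param("no fish supplied")
  curved <- classify_curved(thetas, threshold_deg)
  structure(list(
    n_total = length(thetas),
    n_curved = sum(curved),
    penetrance_pct = 100 * sum(curved) / length(thetas),
    threshold_deg = threshold_deg,
    thetas = thetas), class = "penetrance_summary")
}

#' Penetrance from printed counts
#'
#' Convenience for recomputing published penetrance figures directly
#' from counts, e.g. `penetrance_from_counts(21, 177)` gives 11.86,
#' printed as 11.9%.
#'
#' @param n_curved,n_total counts.
#' @return percentage (unrounded).
#' @export
penetrance_from_counts <- function(n_curved, n_total) {
  n_total <- check_count(n_total, "n_total")
  n_curved <- check_count(n_curved, "n_curved", min = 0L)
  if (n_curved > n_total) stop_param("n_curved exceeds n_total")
  100 * n_curved / n_total
}

#' Dose-response summary of curvature penetrance
#'
#' One row per dose group with sample size, penetrance and mean
#' severity; flags whether estimated penetrance is nondecreasing in
#' dose (the qualitative dose-dependence check).
#'
#' @param groups named list mapping dose label to a numeric vector of
#'   theta angles; names must be coercible to numeric dose for the
#'   trend flag (otherwise input order is used).
#' @param threshold_deg phenotype threshold; default 10.
#' @return tibble (dose, n, n_curved, penetrance_pct, mean_theta)
#'   with attribute `monotone_penetrance`.
#' @export
dose_response <- function(groups, threshold_deg = 10) {
  if (length(groups) == 0L) stop_param("no dose groups supplied")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_param("empty dose group")
  doses <- suppressWarnings(as.numeric(names(groups)))
  ord <- if (all(is.finite(doses))) order(doses) else seq_along(groups)
  rows <- lapply(ord, function(i) {
    p <- penetrance(groups[[i]], threshold_deg)
    tibble::tibble(dose = names(groups)[i], n = p$n_total,
                   n_curved = p$n_curved,
                   penetrance_pct = p$penetrance_pct,
                   mean_theta = mean(groups[[i]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_penetrance") <-
    !is.unsorted(out$penetrance_pct)
  out
}

#' Compare theta angles across groups
#'
#' Two groups: unpaired two-sided Student's t test. More than two:
#' one-way ANOVA. Mirrors the statistics quoted in the curvature
#' figure legends.
#'
#' @param theta_groups named list of numeric vectors (>= 2 groups,
#'   each with >= 2 observations).
#' @param var_equal use the pooled-variance t test (default TRUE,
#'   the classical unpaired Student's t).
#' @return list with `test` ("t" or "anova"), `statistic`, `df`,
#'   `p_value`, and the underlying fit object.
#' @export
compare_groups <- function(theta_groups, var_equal = TRUE) {
  if (length(theta_groups) < 2L) stop_param("need at least 2 groups")
  if (any(vapply(theta_groups, length, integer(1)) < 2L))
    stop_param("each group needs at least 2 observations")
  if (length(theta_groups) == 2L) {
    ht <- stats::t.test(theta_groups[[1]], theta_groups[[2]],
                        var.equal = var_equal)
    list(test = "t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value, fit = ht)
  } else {
    values <- unlist(theta_groups, use.names = FALSE)
    grp <- factor(rep(names(theta_groups),
                      vapply(theta_groups, length, integer(1))))
    fit <- stats::aov(values ~ grp)
    tab <- summary(fit)[[1]]
    list(test = "anova", statistic = tab$`F value`[1],
         df = tab$Df, p_value = tab$`Pr(>F)`[1], fit = fit)
  }
}
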