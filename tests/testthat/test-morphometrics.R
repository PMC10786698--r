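test_that("theta angle matches arc geometry and vector oracles", {
  # straight body
  expect_equal(theta_angle(body_axis(0:10, rep(0, 11))), 0)
  # right-angle polyline head-vertex-tail
  expect_equal(theta_angle(body_axis(c(0, 1, 1), c(0, 0, 1))), 90)
  # arcs: theta equals half the central angle, closed form
  for (th in c(5, 10, 45, 90)) {
    ax <- simulate_midline(midline_sim_params(theta_deg = th))
    expect_equal(theta_angle(ax), th, tolerance = 0.5 / th)
  }
  # duplicate consecutive points collapse; remaining axis is valid
  expect_equal(theta_angle(body_axis(c(0, 0, 1, 2), c(0, 0, 0, 0))), 0)
  expect_error(body_axis(c(1, 1, 1), c(2, 2, 2)),
               class = "scoliquant_param_error")
})

test_that("theta angle is invariant to similarity transforms and reversal", {
  set.seed(21)
  for (i in 1:10) {
    th <- runif(1, 3, 120)
    ax <- simulate_midline(midline_sim_params(theta_deg = th,
                                              noise_sd = 0.01, seed = i))
    ref <- theta_angle(ax)
    ang <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5)
    tx <- runif(1, -10, 10); ty <- runif(1, -10, 10)
    x2 <- sc * (cos(ang) * ax$x - sin(ang) * ax$y) + tx
    y2 <- sc * (sin(ang) * ax$x + cos(ang) * ax$y) + ty
    expect_equal(theta_angle(body_axis(x2, y2)), ref, tolerance = 1e-8)
    # reflection
    expect_equal(theta_angle(body_axis(ax$x, -ax$y)), ref, tolerance = 1e-8)
    # reversal
    expect_equal(theta_angle(body_axis(rev(ax$x), rev(ax$y))), ref,
                 tolerance = 1e-8)
  }
})

test_that("curvature classification is boundary-inclusive at 10 degrees", {
  expect_true(classify_curved(10.0))
  expect_false(classify_curved(9.99))
  expect_false(classify_curved(0))
  expect_equal(classify_curved(c(5, 10, 15), threshold_deg = 10),
               c(FALSE, TRUE, TRUE))
})

test_that("penetrance reproduces printed-count percentages and is monotone in threshold", {
  expect_equal(penetrance_from_counts(21, 177), 11.9, tolerance = 5e-3)
  expect_equal(penetrance_from_counts(17, 127), 13.4, tolerance = 5e-3)
  expect_equal(penetrance_from_counts(4, 32), 12.5)
  expect_equal(penetrance_from_counts(0, 50), 0)

  thetas <- c(2, 4, 9.99, 10, 12, 25, 40)
  p <- penetrance(thetas)
  expect_equal(p$n_curved, 4L)
  expect_equal(p$penetrance_pct, 400 / 7)
  # nonincreasing in threshold
  pens <- vapply(c(0, 5, 10, 20, 30, 50),
                 function(th) penetrance(thetas, th)$penetrance_pct,
                 numeric(1))
  expect_false(is.unsorted(rev(pens)))
  expect_error(penetrance(numeric(0)), class = "scoliquant_param_error")
})

test_that("dose-response summarizes groups and flags monotone penetrance", {
  g <- list("0" = c(2, 3, 12), "1" = c(2, 3, 12))
  dr <- dose_response(g)
  expect_equal(dr$penetrance_pct[1], dr$penetrance_pct[2])
  expect_equal(dr$penetrance_pct[1], penetrance(g[["0"]])$penetrance_pct)
  expect_equal(dr$mean_theta, rep(mean(c(2, 3, 12)), 2))

  # binomial sampling at generating penetrance 0.05 / 0.35 / 0.70
  set.seed(8)
  gen <- function(p, n) ifelse(runif(n) < p, 15 + rexp(n, 0.2), 2 + runif(n, 0, 6))
  doses <- list("0" = gen(0.05, 200), "10" = gen(0.35, 200),
                "100" = gen(0.70, 200))
  dr2 <- dose_response(doses)
  expect_true(attr(dr2, "monotone_penetrance"))
  for (i in seq_along(doses)) {
    p0 <- c(0.05, 0.35, 0.70)[i]
    se <- sqrt(p0 * (1 - p0) / 200)
    expect_lt(abs(dr2$penetrance_pct[i] / 100 - p0), 4 * se)
  }
  expect_error(dose_response(list()), class = "scoliquant_param_error")
})

test_that("group comparison reproduces hand-computed t and F statistics", {
  x <- c(12.1, 9.8, 11.4, 10.9, 13.2)
  y <- c(8.7, 10.2, 9.1, 9.9)
  res <- compare_groups(list(a = x, b = y))
  expect_equal(res$test, "t")
  expect_equal(res$statistic, t_stat_pooled(x, y), tolerance = 1e-6)
  expect_equal(res$df, length(x) + length(y) - 2)

  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  g3 <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(5, 6, 7, 9))
  res3 <- compare_groups(g3)
  expect_equal(res3$test, "anova")
  expect_equal(res3$statistic, anova_f_hand(g3), tolerance = 1e-6)
  expect_error(compare_groups(list(a = 1:3)), class = "scoliquant_param_error")
  expect_error(compare_groups(list(a = 1:3, b = 2)),
               class = "scoliquant_param_error")
})

test_that("two-group comparison holds its nominal type-I error under the null", {
  set.seed(99)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    compare_groups(list(a = rnorm(10), b = rnorm(10)))$p_value < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.02 / 0.05)
})
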