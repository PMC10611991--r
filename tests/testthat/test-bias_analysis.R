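test_that("misclassification correction matches the closed form", {
  # (0.95 - (1 - 0.90)) / (0.98 + 0.90 - 1) = 0.85 / 0.88
  expect_equal(misclassification_correct(95, 100, se = 0.98, sp = 0.90),
               0.85 / 0.88, tolerance = 1e-12)
  expect_equal(misclassification_correct(95, 100, se = 0.98, sp = 0.90),
               0.9659090909090909, tolerance = 1e-12)
  # perfect classifier is the identity
  expect_equal(misclassification_correct(584, 592, se = 1, sp = 1), 584 / 592)
  # an (se, sp) pair incompatible with p_obs surfaces as a value outside [0,1]
  expect_gt(misclassification_correct(99, 100, se = 0.95, sp = 1), 1)
  expect_error(misclassification_correct(50, 100, se = 0.5, sp = 0.5),
               "se \\+ sp")
  expect_error(misclassification_correct(101, 100, se = 0.9, sp = 0.9))
})

test_that("selection adjustment reweights by inverse attendance probability", {
  # equal attendance cancels
  expect_equal(selection_adjust(90, 10, 0.8, 0.8), 0.9)
  # hand-computed: (90/0.95) / (90/0.95 + 10/0.50)
  expect_equal(selection_adjust(90, 10, 0.95, 0.50),
               (90 / 0.95) / (90 / 0.95 + 10 / 0.50), tolerance = 1e-12)
  expect_equal(selection_adjust(90, 10, 0.95, 0.50), 0.8256881,
               tolerance = 1e-6)
  # single-class cohorts are a fixed point
  expect_equal(selection_adjust(50, 0, 0.9, 0.4), 1.0)
  expect_equal(selection_adjust(0, 50, 0.9, 0.4), 0.0)
  expect_error(selection_adjust(90, 10, 0, 0.5), "attendance")
})

test_that("prior constructors enforce the (0, 1] support", {
  expect_error(dist_point(0), "support")
  expect_error(dist_uniform(0.5, 1.2), "support")
  expect_error(dist_uniform(0.9, 0.8), "min > max")
  expect_error(dist_beta(0, 2), "positive")
  expect_error(dist_trapezoidal(0.5, 0.4, 0.6, 0.7), "min <= mode_lo")
  expect_s3_class(dist_trapezoidal(0.8, 0.9, 0.95, 1), "qba_dist")
})

test_that("trapezoidal draws follow the analytic mean and support", {
  a <- 0.6; b <- 0.8; cc <- 0.9; d <- 1.0
  dist <- dist_trapezoidal(a, b, cc, d)
  x <- withr::with_seed(123, draw_dist(dist, 2e5))
  expect_true(all(x >= a & x <= d))
  mean_cf <- (d^2 + d * cc + cc^2 - a^2 - a * b - b^2) / (3 * (d + cc - a - b))
  expect_equal(mean(x), mean_cf, tolerance = 2e-3)
  # degenerate trapezoid collapses to a point mass
  expect_equal(draw_dist(dist_trapezoidal(0.7, 0.7, 0.7, 0.7), 3), rep(0.7, 3))
})

test_that("null-bias point masses recover the crude estimate", {
  params <- bias_parameters(n_iter = 50000, seed = 21)
  res <- run_qba(584, 592, params)
  expect_equal(res$point_estimate, 584 / 592, tolerance = 0.002)
  expect_equal(res$n_discarded, 0L)
  # interval width is driven only by the binomial error step
  expect_lt(res$sim_high - res$sim_low, 4 * sqrt(0.986 * 0.014 / 592) * 2)
})

test_that("a single-iteration run is reproduced bit-exactly", {
  params <- bias_parameters(se_dist = dist_uniform(0.95, 1),
                            sp_dist = dist_uniform(0.95, 1),
                            n_iter = 1, seed = 77)
  a <- run_qba(600, 637, params)
  b <- run_qba(600, 637, params)
  expect_identical(a$point_estimate, b$point_estimate)
  expect_identical(a[c("sim_low", "sim_high", "n_kept")],
                   b[c("sim_low", "sim_high", "n_kept")])
})

test_that("lowering specificity strictly lowers the corrected proportion", {
  p_obs <- 0.95
  corrected <- sapply(c(1, 0.95, 0.9, 0.85), function(sp) {
    misclassification_correct(p_obs * 1000, 1000, se = 0.98, sp = sp)
  })
  expect_true(all(diff(corrected) < 0))
  # and the same ordering propagates through a full run with point masses
  meds <- sapply(c(1, 0.9), function(sp) {
    run_qba(605, 637, bias_parameters(
      se_dist = dist_point(0.98), sp_dist = dist_point(sp),
      n_iter = 20000, seed = 5))$point_estimate
  })
  expect_lt(meds[2], meds[1])
})

test_that("impossible draws are discarded and tallied, or truncated on request", {
  # p_obs = 0.99 with sp = 1 is impossible whenever se < 0.99
  params <- bias_parameters(se_dist = dist_uniform(0.9, 1), sp_dist = dist_point(1),
                            n_iter = 10000, seed = 8)
  res <- run_qba(990, 1000, params)
  expect_gt(res$n_discarded, 0)
  expect_equal(res$n_kept + res$n_discarded, 10000L)
  trunc <- run_qba(990, 1000, bias_parameters(
    se_dist = dist_uniform(0.9, 1), sp_dist = dist_point(1),
    n_iter = 10000, seed = 8, impossible_draw_policy = "truncate"))
  expect_equal(trunc$n_discarded, 0L)
  # an entirely incompatible prior region fails loudly
  expect_error(run_qba(999, 1000, bias_parameters(
    se_dist = dist_point(0.9), sp_dist = dist_point(1),
    n_iter = 100, seed = 1)), "incompatible")
})

test_that("widening a prior never narrows the simulation interval", {
  width <- function(se_dist, seed) {
    r <- run_qba(605, 637, bias_parameters(
      se_dist = se_dist, sp_dist = dist_point(0.95),
      attend_given_complete = dist_point(0.93),
      attend_given_incomplete = dist_point(0.8),
      n_iter = 20000, seed = seed))
    r$sim_high - r$sim_low
  }
  for (seed in 1:5) {
    w_point <- width(dist_point(0.95), seed)
    w_wide <- width(dist_uniform(0.9, 1), seed)
    expect_gte(w_wide, w_point - 1e-3)
  }
})

test_that("the trace retains per-iteration draws consistent with the summaries", {
  params <- bias_parameters(se_dist = dist_uniform(0.92, 1),
                            sp_dist = dist_uniform(0.8, 1),
                            n_iter = 2000, seed = 31)
  res <- run_qba(605, 637, params, keep_trace = TRUE)
  expect_equal(nrow(res$trace), 2000)
  expect_equal(sum(res$trace$kept), res$n_kept)
  kept <- res$trace$p_final[res$trace$kept]
  expect_equal(median(kept), res$point_estimate)
})
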