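test_that("generation is bit-identical for the same config and differs across seeds", {
  cfg <- cohort_config(n = 200, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(n = 200, seed = 43)
  expect_false(identical(generate_cohort(cfg2)$records, a$records))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n = 0), "n: must be a positive integer")
  expect_error(cohort_config(site_probs = c(nigeria = 0.5, southeast_asia = 0.4,
                                            argentina = 0.2)),
               "site_probs")
  expect_error(cohort_config(selfreport_sensitivity = 1.2),
               "selfreport_sensitivity")
  expect_error(cohort_config(fu2_attendance_prob = c(complete = 0, incomplete = 1)),
               "fu2_attendance_prob")
  expect_error(cohort_config(nonexistent_knob = 1), "unknown config fields")
})

test_that("with no noise channels the observed crude equals the truth exactly", {
  cfg <- cohort_config(n = 400, seed = 5,
                       selfreport_sensitivity = 1, selfreport_specificity = 1,
                       fu1_attendance_prob = 1,
                       fu2_attendance_prob = c(complete = 1, incomplete = 1),
                       proc_prob = 0)
  coh <- generate_cohort(cfg)
  cls <- classify_effectiveness(coh$records, "last_recorded")
  expect_equal(mean(cls == "complete_no_procedure"),
               mean(coh$truth$true_complete))
  # and the truth never leaks into the observed record columns
  expect_false("true_complete" %in% names(coh$records))
})

test_that("field streams are disjoint: downstream knobs do not perturb upstream draws", {
  cfg <- cohort_config(n = 300, seed = 9)
  a <- generate_cohort(cfg)
  cfg2 <- cohort_config(n = 300, seed = 9,
                        care_seeking_prob = c(warning = 0.9, none = 0.9),
                        side_effect_probs = c(pain = 1))
  b <- generate_cohort(cfg2)
  expect_identical(a$truth, b$truth)
  expect_identical(a$records$site, b$records$site)
  expect_identical(a$records$fu2_attended, b$records$fu2_attended)
  expect_identical(a$records$fu1_status, b$records$fu1_status)
})

test_that("imperfect sensitivity with perfect specificity biases the crude downward by (1-Se)p", {
  se <- 0.90
  cfg0 <- cohort_config(n = 4000, selfreport_sensitivity = se,
                        selfreport_specificity = 1,
                        fu1_attendance_prob = 1,
                        fu2_attendance_prob = c(complete = 1, incomplete = 1),
                        proc_prob = 0)
  crude <- truth <- numeric(30)
  for (s in seq_len(30)) {
    cfg0$seed <- s
    coh <- generate_cohort(cfg0)
    cls <- classify_effectiveness(coh$records, "last_recorded")
    crude[s] <- mean(cls == "complete_no_procedure")
    truth[s] <- mean(coh$truth$true_complete)
  }
  # E[crude] = Se * p, so the bias is -(1 - Se) * p
  expect_lt(mean(crude), mean(truth))
  expect_equal(mean(truth - crude), (1 - se) * mean(truth), tolerance = 0.02)
})

test_that("default configuration reproduces the reference margins in expectation", {
  cfg <- default_cohort_config()
  expect_equal(sum(cfg$site_probs), 1)
  expect_equal(sum(cfg$duration_probs), 1)
  expect_equal(unname(cfg$duration_probs["lt7"] * cfg$n), 317, tolerance = 1e-9)
  expect_equal(unname(cfg$regimen_probs["endorsed_3x800"] * cfg$n), 532,
               tolerance = 1e-9)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$records), 637)
  # expected second-follow-up attrition is ~45 of 637
  p_true <- mean(coh$truth$true_complete)
  e_missing <- 637 * (p_true * (1 - cfg$fu2_attendance_prob["complete"]) +
                        (1 - p_true) * (1 - cfg$fu2_attendance_prob["incomplete"]))
  expect_equal(unname(e_missing), 45, tolerance = 4)
})

test_that("generated cohorts pass validation and write truth separately", {
  coh <- generate_cohort(cohort_config(n = 150, seed = 2))
  expect_silent(validate_cohort(coh$records))
  path <- tempfile(fileext = ".csv")
  write_generated_cohort(coh, path)
  expect_true(file.exists(sub("\\.csv$", "_truth.csv", path)))
  obs <- read.csv(path, nrows = 1)
  expect_false("true_complete" %in% names(obs))
})

test_that("generator configuration round-trips through its YAML file format", {
  cfg <- cohort_config(n = 123, seed = 55,
                       selfreport_sensitivity = 0.97)
  path <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n, 123)
  expect_equal(back$selfreport_sensitivity, 0.97)
  expect_equal(back$true_completion_prob, cfg$true_completion_prob)
  expect_equal(back$expulsion_dist, cfg$expulsion_dist)
  # a cohort generated from the reloaded config is identical
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
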