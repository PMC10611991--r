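test_that("wilson interval reproduces the published primary-endpoint bounds", {
  expect_equal(round_half_up(100 * wilson_interval(625, 637), 1), c(96.7, 98.9),
               ignore_attr = TRUE)
  expect_equal(round_half_up(100 * wilson_interval(605, 635), 1), c(93.3, 96.7),
               ignore_attr = TRUE)
})

test_that("wilson interval boundary and symmetry properties hold", {
  expect_identical(unname(wilson_interval(0, 10)[1]), 0)
  expect_identical(unname(wilson_interval(10, 10)[2]), 1)
  for (case in list(c(3, 17), c(0, 5), c(50, 120), c(611, 637))) {
    x <- case[1]; n <- case[2]
    ci <- wilson_interval(x, n)
    mirror <- wilson_interval(n - x, n)
    expect_equal(unname(ci), unname(rev(1 - mirror)), tolerance = 1e-12)
    p <- x / n
    expect_lte(ci[1], p); expect_gte(ci[2], p)
  }
  expect_error(wilson_interval(3, 0), "denominator")
  expect_error(wilson_interval(5, 3), "numerator")
})

test_that("wilson bounds agree with the score-equation root-finder", {
  set.seed(101)
  for (n in c(1, 2, 7, 33, 120, 637)) {
    for (x in unique(c(0, 1, n %/% 2, n - 1, n, sample(0:n, min(5, n + 1))))) {
      expect_equal(unname(wilson_interval(x, n)), oracle_wilson_root(x, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("clopper-pearson brackets wilson and respects its exact coverage bounds", {
  for (case in list(c(4, 20), c(625, 637), c(0, 12))) {
    w <- wilson_interval(case[1], case[2])
    cp <- clopper_pearson_interval(case[1], case[2])
    expect_lte(cp[1], w[1] + 1e-12)   # exact interval is never narrower
    expect_gte(cp[2], w[2] - 1e-12)
  }
  res <- endpoint_result(6, 637, method = "clopper_pearson")
  expect_identical(res$method, "clopper_pearson")
  expect_true(res$ci_low <= res$proportion && res$proportion <= res$ci_high)
})

test_that("percent rounding is half away from zero", {
  expect_equal(round_half_up(c(0.25, 0.35, -0.25, 10.55), 1),
               c(0.3, 0.4, -0.3, 10.6))
  expect_equal(round_half_up(98.05), 98.1)
})

test_that("tabulate produces policy-consistent denominators and percentages", {
  cohort <- reference_cohort()
  tab <- tabulate_records(cohort, "effectiveness_last")
  expect_equal(unique(tab$denominator), 637)
  expect_equal(tab$count[tab$row == "complete_no_procedure"], 625)
  expect_equal(tab$pct[tab$row == "complete_no_procedure"], 98.1)
  expect_equal(sum(tab$pct), 100, tolerance = 0.2)

  strat <- tabulate_records(cohort, "effectiveness_last", strata = "duration_weeks")
  expect_equal(unique(strat$denominator[strat$stratum == "lt7"]), 317)
  expect_equal(unique(strat$denominator[strat$stratum == "12to16"]), 23)

  excl <- tabulate_records(cohort, "education", policy = "missing_excluded")
  expect_equal(unique(excl$denominator), 637 - 5)
  expect_false("missing" %in% excl$row)
  incl <- tabulate_records(cohort, "education")
  expect_equal(unique(incl$denominator), 637)
  expect_equal(incl$count[incl$row == "missing"], 5)
})

test_that("tabulate is order-invariant, handles empty cohorts, and echoes unknown names", {
  cohort <- reference_cohort()
  shuffled <- cohort[rev(seq_len(nrow(cohort))), ]
  a <- tabulate_records(cohort, "effectiveness_last")
  b <- tabulate_records(shuffled, "effectiveness_last")
  expect_equal(dplyr::arrange(a, row), dplyr::arrange(b, row))
  empty <- tabulate_records(cohort[0, ], "site")
  expect_equal(nrow(empty), 0)
  expect_error(tabulate_records(cohort, "no_such_field"), "no_such_field")
})

test_that("expulsion-within-window proportion counts only observed expulsions", {
  cohort <- reference_cohort()
  res <- proportion_expelled_within(cohort, 24)
  expect_equal(res$numerator, 544)
  expect_equal(res$denominator, 637)
  expect_equal(round_half_up(100 * res$proportion), 85.4)
  all_observed <- proportion_expelled_within(cohort, Inf)
  expect_equal(all_observed$numerator, sum(cohort$expulsion_observed, na.rm = TRUE))
  expect_error(proportion_expelled_within(cohort, 0))
})

test_that("plain-text rendering aligns every stratum column", {
  tab <- tabulate_records(reference_cohort(), "effectiveness_last",
                          strata = "regimen")
  txt <- format_frequency_table(tab, title = "effectiveness by regimen")
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "effectiveness by regimen")
  expect_match(txt, "529")
  expect_match(txt, "96 ")
})
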