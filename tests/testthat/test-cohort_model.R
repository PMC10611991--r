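rec_template <- function(...) {
  rec <- reference_cohort()[1, ]
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

test_that("classification precedence: intervention overrides a completion self-report", {
  r <- rec_template(fu2_status = "complete", procedural_intervention = "mva",
                    intervention_timing = "fu2")
  expect_equal(as.character(classify_effectiveness(r, "fu2")),
               "complete_with_procedure")
  # intervention reported in the second window does not count at first follow-up
  r$fu1_status <- "complete"
  expect_equal(as.character(classify_effectiveness(r, "fu1")),
               "complete_no_procedure")
  # but one in the first window counts at both
  r$intervention_timing <- "fu1"
  expect_equal(as.character(classify_effectiveness(r, "fu1")),
               "complete_with_procedure")
  # self-reported not-complete keeps its own class even with an intervention
  r$fu2_status <- "not_complete_or_unsure"
  expect_equal(as.character(classify_effectiveness(r, "fu2")),
               "not_complete_or_unsure")
})

test_that("last recorded follow-up carries the 1-week class forward on attrition", {
  r <- rec_template(fu1_status = "complete", fu2_attended = FALSE,
                    fu2_status = NA_character_, fu2_days = NA_integer_,
                    procedural_intervention = "none",
                    intervention_timing = NA_character_)
  expect_equal(as.character(classify_effectiveness(r, "last_recorded")),
               "complete_no_procedure")
  r$fu1_status <- "not_complete_or_unsure"
  expect_equal(as.character(classify_effectiveness(r, "last_recorded")),
               "not_complete_or_unsure")
  # and equals the 3-week class whenever the participant attended it
  cohort <- reference_cohort()
  attended <- cohort[cohort$fu2_attended, ]
  expect_equal(classify_effectiveness(attended, "last_recorded"),
               classify_effectiveness(attended, "fu2"))
})

test_that("class counts partition the time-point denominators", {
  cohort <- reference_cohort()
  f1 <- cohort[cohort$fu1_attended, ]
  expect_equal(sum(table(classify_effectiveness(f1, "fu1"))), nrow(f1))
  expect_equal(nrow(f1), 635)
  f2 <- cohort[cohort$fu2_attended, ]
  expect_equal(sum(table(classify_effectiveness(f2, "fu2"))), nrow(f2))
  expect_equal(nrow(f2), 592)
  expect_equal(sum(table(classify_effectiveness(cohort, "last_recorded"))), 637)
})

test_that("warning-sign and adverse-event composites have OR semantics", {
  r <- rec_template(ws_heavy_bleeding = FALSE, ws_unrelieved_pain = FALSE,
                    ws_fever = FALSE, ws_foul_discharge = FALSE)
  expect_false(composite_warning_sign(r))
  r$ws_fever <- TRUE
  expect_true(composite_warning_sign(r))
  # multiple signs still count once
  r$ws_foul_discharge <- TRUE
  expect_true(composite_warning_sign(r))

  a <- rec_template(ae_iv_fluids = FALSE, ae_transfusion = FALSE,
                    ae_overnight_stay = FALSE)
  expect_false(composite_adverse_event(a))
  a$ae_iv_fluids <- TRUE
  expect_true(composite_adverse_event(a))
})

test_that("fully missing safety data propagates as missing, partial does not mask a TRUE", {
  r <- rec_template(ws_heavy_bleeding = NA, ws_unrelieved_pain = NA,
                    ws_fever = NA, ws_foul_discharge = NA)
  expect_true(is.na(composite_warning_sign(r)))
  r$ws_fever <- TRUE
  expect_true(composite_warning_sign(r))
})

test_that("composite counts bracket the component counts", {
  cohort <- reference_cohort()
  comp <- sum(composite_warning_sign(cohort), na.rm = TRUE)
  per_sign <- colSums(cohort[, c("ws_heavy_bleeding", "ws_unrelieved_pain",
                                 "ws_fever", "ws_foul_discharge")],
                      na.rm = TRUE)
  expect_gte(comp, max(per_sign))
  expect_lte(comp, sum(per_sign))
})

test_that("cohort validation reports all offending rows before failing", {
  cohort <- reference_cohort()
  bad <- cohort
  bad$site[3] <- "atlantis"
  bad$fu2_status[which(!bad$fu2_attended)[1]] <- "complete"
  err <- tryCatch(validate_cohort(bad), error = function(e) conditionMessage(e))
  expect_match(err, "invalid site")
  expect_match(err, "fu2_status present without fu2 attendance")
})

test_that("cohort CSV round-trips losslessly with its dictionary", {
  cohort <- reference_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_true(file.exists(sub("\\.csv$", "_dictionary.csv", path)))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})
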