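# Participant data model and endpoint derivation.
#
# A cohort is a tibble with one row per enrolled participant. Enum fields are
# stored as lowercase tokens; multi-select fields as ";"-joined token sets;
# missing values as NA (empty cells on disk).

#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# -- enum vocabularies --------------------------------------------------------

effectiveness_levels <- c(
  "complete_no_procedure", "complete_with_procedure",
  "not_complete_or_unsure", "missing"
)

duration_levels <- c("lt7", "7to_lt9", "9to_lt12", "12to16")
site_levels     <- c("argentina", "nigeria", "southeast_asia")
age_levels      <- c("lt20", "20_24", "25_29", "30_34", "ge35")
regimen_levels  <- c("endorsed_3x800", "other")
education_levels <- c("primary", "secondary", "more_than_secondary")
intervention_levels <- c("none", "mva", "dc")

warning_sign_fields <- c(
  "ws_heavy_bleeding", "ws_unrelieved_pain", "ws_fever", "ws_foul_discharge"
)
adverse_event_fields <- c("ae_iv_fluids", "ae_transfusion", "ae_overnight_stay")

#' Column specification of a participant cohort
#'
#' Returns the data dictionary for the cohort format: one row per column with
#' its type and, for enum columns, the allowed tokens. The same dictionary is
#' written alongside every cohort CSV emitted by the package.
#'
#' @return A tibble with columns `field`, `type`, `values`, `description`.
#' @export
cohort_dictionary <- function() {
  tibble::tribble(
    ~field, ~type, ~values, ~description,
    "participant_id", "character", "", "opaque participant identifier",
    "site", "enum", paste(site_levels, collapse = "|"), "recruitment site",
    "age_group", "enum", paste(age_levels, collapse = "|"), "age band, years",
    "education", "enum", paste(education_levels, collapse = "|"),
      "highest schooling completed; empty = missing",
    "prior_attempt", "enum", "yes|no", "prior attempt to end this pregnancy",
    "preg_confirm", "set", "test;missed_period;ultrasound;bimanual",
      "pregnancy ascertainment methods (multi-select)",
    "duration_weeks", "enum", paste(duration_levels, collapse = "|"),
      "pregnancy duration bin at first dose",
    "regimen", "enum", paste(regimen_levels, collapse = "|"),
      "endorsed_3x800 = 3 x 800 ug misoprostol, 3 h apart",
    "route", "enum", "sublingual|other", "administration route",
    "source", "enum", "pharmacy|other", "where medications were obtained",
    "fu1_attended", "logical", "", "completed the ~1-week follow-up interview",
    "fu1_status", "enum", "complete|not_complete_or_unsure",
      "self-reported completion at first follow-up; empty = missing",
    "fu1_days", "integer", "", "days from first dose to first follow-up",
    "fu2_attended", "logical", "", "completed the ~3-week follow-up interview",
    "fu2_status", "enum", "complete|not_complete_or_unsure",
      "self-reported completion at second follow-up; empty = missing",
    "fu2_days", "integer", "", "days from first dose to second follow-up",
    "procedural_intervention", "enum", paste(intervention_levels, collapse = "|"),
      "manual vacuum aspiration or dilation & curettage/evacuation",
    "intervention_timing", "enum", "fu1|fu2",
      "follow-up window in which the intervention was reported",
    "ws_heavy_bleeding", "logical", "", "bleeding >2 pads/h for >2 h",
    "ws_unrelieved_pain", "logical", "", "pain unrelieved by pain medication",
    "ws_fever", "logical", "", "fever >38 C for >24 h",
    "ws_foul_discharge", "logical", "", "foul-smelling vaginal discharge",
    "ae_iv_fluids", "logical", "", "received intravenous fluids",
    "ae_transfusion", "logical", "", "received a blood transfusion",
    "ae_overnight_stay", "logical", "", "overnight hospital stay",
    "sought_care", "logical", "", "ever sought follow-up health care",
    "care_facility", "enum", "clinic_hospital|pharmacy_lab|other",
      "facility type where care was sought",
    "care_reasons", "set", "confirm_completion;symptom_concern;other",
      "reasons for seeking care (multi-select)",
    "care_treatments", "set",
      paste("observation;additional_miso;antibiotics;pain_medication;",
            "other_medications;mva;dc;ultrasound;iv_fluids;transfusion;",
            "overnight_stay;none", sep = ""),
      "treatments received when seeking care (multi-select)",
    "disclosure", "enum",
      "told_nothing|said_miscarriage|told_them|they_found_out|other",
      "whether the clinician knew the abortion was self-managed",
    "expulsion_observed", "logical",
      "", "noticed products of conception; empty = missing data",
    "time_to_expulsion_h", "numeric",
      "", "hours from first dose to expulsion; empty when not observed",
    "bleeding_days", "integer", "", "days of any bleeding",
    "heavy_bleeding_days", "integer", "", "days of heavy bleeding",
    "cramping_days", "numeric", "", "days of cramping",
    "side_effects", "set",
      paste("pain;nausea;fever;diarrhea;chills;vomiting;itchiness;",
            "breathing;facial_numbness;sweaty_hands", sep = ""),
      "self-reported side effects (multi-select)"
  )
}

# -- validation ---------------------------------------------------------------

#' Validate a participant cohort
#'
#' Checks column presence, enum vocabularies, and the record invariants
#' (a participant who did not attend a follow-up cannot carry a self-report
#' status for it; expulsion time is present iff products of conception were
#' noticed). All rows are checked before failing so a malformed file yields a
#' complete list of row-level diagnostics.
#'
#' @param records cohort tibble (see [cohort_dictionary()]).
#' @return `records`, invisibly, if valid; otherwise an error whose message
#'   lists every offending row.
#' @export
validate_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  dict <- cohort_dictionary()
  missing_cols <- setdiff(dict$field, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        "rows ", paste(utils::head(rows, 10), collapse = ","),
        if (length(rows) > 10) ",..." else "", ": ", what))
    }
  }
  check_enum <- function(field, levels) {
    v <- records[[field]]
    note(which(!is.na(v) & !v %in% levels), paste0("invalid ", field))
  }
  check_enum("site", site_levels)
  check_enum("age_group", age_levels)
  check_enum("duration_weeks", duration_levels)
  check_enum("regimen", regimen_levels)
  check_enum("education", education_levels)
  check_enum("prior_attempt", c("yes", "no"))
  check_enum("fu1_status", c("complete", "not_complete_or_unsure"))
  check_enum("fu2_status", c("complete", "not_complete_or_unsure"))
  check_enum("procedural_intervention", intervention_levels)
  check_enum("intervention_timing", c("fu1", "fu2"))

  note(which(is.na(records$duration_weeks)), "duration_weeks missing")
  note(which(!records$fu2_attended & !is.na(records$fu2_status)),
       "fu2_status present without fu2 attendance")
  note(which(!records$fu1_attended & !is.na(records$fu1_status)),
       "fu1_status present without fu1 attendance")
  note(which(records$expulsion_observed %in% TRUE &
               is.na(records$time_to_expulsion_h)),
       "expulsion observed but time_to_expulsion_h missing")
  note(which(records$expulsion_observed %in% FALSE &
               !is.na(records$time_to_expulsion_h)),
       "time_to_expulsion_h present but expulsion not observed")
  note(which(!is.na(records$time_to_expulsion_h) &
               records$time_to_expulsion_h < 0),
       "negative time_to_expulsion_h")

  if (length(problems) > 0) {
    stop("invalid cohort:\n", paste(problems, collapse = "\n"))
  }
  invisible(records)
}

# -- endpoint derivation ------------------------------------------------------

#' Classify effectiveness at a follow-up time point
#'
#' The primary outcome is abortion completion without procedural intervention.
#' Classification precedence per participant: a procedural intervention (MVA
#' or D&C/evacuation) reported by the queried time point together with a
#' self-report of completion yields `complete_with_procedure`; a self-report
#' of completion with no intervention yields `complete_no_procedure`; a
#' self-report of "not complete or not sure" is classified as such regardless
#' of intervention; anything else is `missing`. At `last_recorded` the
#' 3-week classification is used when the participant attended the second
#' follow-up and the 1-week classification is carried forward otherwise.
#'
#' A participant who did not attend the queried follow-up is classified
#' `missing` at that time point; time-point denominators are handled by
#' [derive_endpoints()].
#'
#' @param records cohort tibble.
#' @param timepoint one of `"fu1"`, `"fu2"`, `"last_recorded"`.
#' @return factor with levels `complete_no_procedure`,
#'   `complete_with_procedure`, `not_complete_or_unsure`, `missing`.
#' @export
classify_effectiveness <- function(records, timepoint = c("fu1", "fu2", "last_recorded")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "last_recorded") {
    cls_fu1 <- classify_effectiveness(records, "fu1")
    cls_fu2 <- classify_effectiveness(records, "fu2")
    out <- ifelse(records$fu2_attended %in% TRUE,
                  as.character(cls_fu2), as.character(cls_fu1))
    return(factor(out, levels = effectiveness_levels))
  }
  status <- records[[paste0(timepoint, "_status")]]
  # intervention counts toward fu1 only if reported in the first window;
  # toward fu2 (and hence last recorded) if reported in either window
  had_proc <- !is.na(records$procedural_intervention) &
    records$procedural_intervention != "none" &
    !is.na(records$intervention_timing) &
    (timepoint == "fu2" | records$intervention_timing == "fu1")
  out <- rep("missing", nrow(records))
  out[!is.na(status) & status == "complete" & had_proc] <- "complete_with_procedure"
  out[!is.na(status) & status == "complete" & !had_proc] <- "complete_no_procedure"
  # self-report of not-complete/not-sure takes its own class even if an
  # intervention was reported (no such cell is identifiable from aggregate
  # published tables; see the methods vignette)
  out[!is.na(status) & status == "not_complete_or_unsure"] <- "not_complete_or_unsure"
  factor(out, levels = effectiveness_levels)
}

#' Warning-sign composite
#'
#' TRUE if any of the four potential warning signs (heavy bleeding soaking
#' more than 2 pads/h for over 2 h, pain unrelieved by medication, fever above
#' 38 C for over 24 h, foul-smelling discharge) was reported at either
#' follow-up. NA only when no sign is reported and at least one sign field is
#' missing; a participant with entirely missing safety data stays NA and is
#' retained in descriptive denominators.
#'
#' @param records cohort tibble.
#' @return logical vector, one element per participant.
#' @export
composite_warning_sign <- function(records) {
  or_composite(records, warning_sign_fields)
}

#' Adverse-event composite
#'
#' TRUE if the participant received any of the three treatments taken to
#' indicate a potential adverse event: intravenous fluids, blood transfusion,
#' or an overnight hospital stay. Missingness semantics as in
#' [composite_warning_sign()].
#'
#' @param records cohort tibble.
#' @return logical vector.
#' @export
composite_adverse_event <- function(records) {
  or_composite(records, adverse_event_fields)
}

or_composite <- function(records, fields) {
  m <- as.matrix(records[, fields, drop = FALSE])
  storage.mode(m) <- "logical"
  any_true <- rowSums(m, na.rm = TRUE) > 0
  any_na   <- rowSums(is.na(m)) > 0
  ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
}

#' Effectiveness endpoints at all three time points
#'
#' Computes the primary-outcome numerator, denominator and confidence interval
#' at first follow-up (denominator: participants who attended it), second
#' follow-up (likewise) and last recorded follow-up (denominator: the full
#' cohort, using the carry-forward rule).
#'
#' @param records cohort tibble.
#' @param conf_method `"wilson"` (default) or `"clopper_pearson"`.
#' @param alpha two-sided type-I error for the CI.
#' @return tibble with one row per time point: `timepoint`, `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`, `method`.
#' @export
derive_endpoints <- function(records, conf_method = "wilson", alpha = 0.05) {
  rows <- lapply(c("fu1", "fu2", "last_recorded"), function(tp) {
    in_denom <- switch(tp,
      fu1 = records$fu1_attended %in% TRUE,
      fu2 = records$fu2_attended %in% TRUE,
      last_recorded = rep(TRUE, nrow(records)))
    cls <- classify_effectiveness(records[in_denom, , drop = FALSE], tp)
    res <- endpoint_result(sum(cls == "complete_no_procedure"), sum(in_denom),
                           alpha = alpha, method = conf_method)
    tibble::tibble(timepoint = tp, !!!res)
  })
  dplyr::bind_rows(rows)
}

# -- cohort I/O ---------------------------------------------------------------

#' Write a cohort to CSV (with its data dictionary)
#'
#' Enum tokens are written as-is, logicals as `true`/`false`, missing values
#' as empty cells. A `<stem>_dictionary.csv` is emitted alongside.
#'
#' @param records cohort tibble.
#' @param path output CSV path.
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                                                   ifelse(out[[nm]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  dict_path <- sub("\\.csv$", "_dictionary.csv", path)
  if (identical(dict_path, path)) dict_path <- paste0(path, ".dictionary.csv")
  utils::write.csv(cohort_dictionary(), dict_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @param validate run [validate_cohort()] after reading (default TRUE).
#' @return cohort tibble.
#' @export
read_cohort <- function(path, validate = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "")
  dict <- cohort_dictionary()
  rec <- tibble::as_tibble(raw)
  for (i in seq_len(nrow(dict))) {
    f <- dict$field[i]
    if (!f %in% names(rec)) next
    rec[[f]] <- switch(dict$type[i],
      logical = rec[[f]] == "true",
      integer = as.integer(rec[[f]]),
      numeric = as.numeric(rec[[f]]),
      rec[[f]])
  }
  if (validate) validate_cohort(rec)
  rec
}
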