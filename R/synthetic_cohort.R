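# Seeded synthetic-cohort generator.
#
# The generator draws a latent true completion status for every participant
# and then passes it through the two observation channels the bias analysis
# targets: self-report with sensitivity/specificity (Se, Sp), and
# outcome-dependent attendance at the second follow-up. Truth is returned as
# a separate table and never written into the observed record file, so
# misclassification-recovery tests have an oracle the real study lacks.
#
# Every field is drawn from its own RNG substream (derived from the config
# seed and a fixed per-field offset), so adding a field to the generator does
# not perturb the draws of earlier fields.

#' Synthetic cohort configuration
#'
#' Builds and validates the parameter set of the generator. All probability
#' vectors must sum to 1 (tolerance 1e-9); `selfreport_sensitivity` /
#' `selfreport_specificity` must lie in (0, 1].
#'
#' Defaults are those of [default_cohort_config()] applied on top of any
#' overrides given here.
#'
#' @param n cohort size.
#' @param site_probs,duration_probs,regimen_probs named probability vectors
#'   over the site, pregnancy-duration and regimen vocabularies.
#' @param true_completion_prob 4 x 2 matrix (duration bin x regimen) of
#'   probabilities that the abortion truly completes without intervention.
#' @param selfreport_sensitivity,selfreport_specificity Se = P(report
#'   complete | truly complete), Sp = P(report not complete/unsure | truly
#'   not complete).
#' @param fu1_attendance_prob probability of completing the 1-week follow-up.
#' @param fu2_attendance_prob named vector `c(complete=, incomplete=)`:
#'   probability of completing the 3-week follow-up given true outcome.
#' @param proc_prob probability of a procedural intervention; `proc_fu1_frac`
#'   the fraction of interventions occurring in the first follow-up window.
#' @param warning_sign_probs 4 x 2 matrix (sign x true outcome) of per-sign
#'   probabilities.
#' @param adverse_event_probs length-3 vector (IV fluids, transfusion,
#'   overnight stay).
#' @param care_seeking_prob named vector `c(warning=, none=)`.
#' @param expulsion_dist tibble with columns `category` (`not_observed`,
#'   `missing`, or a bin), `lo`, `hi` (hours; NA for non-bins) and `prob`;
#'   times are uniform within their bin.
#' @param seed integer RNG seed.
#' @param ... further generator knobs (demographics, symptom-duration and
#'   side-effect distributions); see [default_cohort_config()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n = NULL, ...) {
  cfg <- default_cohort_config()
  overrides <- c(if (!is.null(n)) list(n = n), list(...))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_cohort_config(cfg)
}

#' Default configuration calibrated to the reference study margins
#'
#' Site mix 591/45/1 (Nigeria / Southeast Asia / Argentina), duration mix
#' 317/205/92/23 across the <7, 7-<9, 9-<12 and 12-16 week bins, regimen mix
#' 532/105 (endorsed 3 x 800 ug vs other), 2.5/97.5-style expulsion-time
#' bins, and true completion probabilities per duration x regimen stratum
#' consistent with the published stratum effectiveness. Expected second
#' follow-up attrition is 45 of 637, differential by true outcome.
#'
#' @return list of class `cohort_config`.
#' @export
default_cohort_config <- function() {
  n_ref <- 637
  cfg <- list(
    n = n_ref,
    seed = 20230637L,
    site_probs = c(nigeria = 591, southeast_asia = 45, argentina = 1) / n_ref,
    duration_probs = c(lt7 = 317, `7to_lt9` = 205, `9to_lt12` = 92,
                       `12to16` = 23) / n_ref,
    regimen_probs = c(endorsed_3x800 = 532, other = 105) / n_ref,
    # duration-stratum completion rates shifted on the odds scale to match
    # the endorsed/other split (529/532 vs 96/105)
    true_completion_prob = matrix(
      c(0.9982, 0.9928, 0.9936, 0.9582,    # endorsed_3x800
        0.9702, 0.8922, 0.9033, 0.5798),   # other
      nrow = 4, dimnames = list(duration_levels, regimen_levels)),
    selfreport_sensitivity = 0.99,
    selfreport_specificity = 0.95,
    fu1_attendance_prob = 635 / n_ref,
    fu2_attendance_prob = c(complete = 0.932, incomplete = 0.80),
    proc_prob = 3 / n_ref,
    proc_fu1_frac = 1 / 3,
    warning_sign_probs = matrix(
      c(0.018, 0.028, 0.005, 0.030,        # given truly complete
        0.15, 0.20, 0.03, 0.20),           # given truly incomplete
      nrow = 4, dimnames = list(warning_sign_fields, c("complete", "incomplete"))),
    adverse_event_probs = c(ae_iv_fluids = 6, ae_transfusion = 0.2,
                            ae_overnight_stay = 3) / n_ref,
    care_seeking_prob = c(warning = 0.442, none = 0.216),
    expulsion_dist = tibble::tibble(
      category = c("not_observed", "lt8", "8to12", "12to16", "16to24",
                   "gt24", "missing"),
      lo = c(NA, 0, 8, 12, 16, 24, NA),
      hi = c(NA, 8, 12, 16, 24, 48, NA),
      prob = c(48, 79, 311, 96, 58, 44, 1) / n_ref),
    age_probs = c(lt20 = 23, `20_24` = 157, `25_29` = 227, `30_34` = 119,
                  ge35 = 111) / n_ref,
    education_probs = c(primary = 13, secondary = 263,
                        more_than_secondary = 356, missing = 5) / n_ref,
    prior_attempt_probs = c(no = 600, yes = 35, missing = 2) / n_ref,
    confirm_probs = c(test = 617, missed_period = 1, ultrasound = 22,
                      bimanual = 1) / n_ref,
    route_probs = c(sublingual = 626, other = 11) / n_ref,
    source_probs = c(pharmacy = 471, other = 166) / n_ref,
    bleeding_days_dist = tibble::tibble(
      value = c(0L, 2L, 5L, 8L, 11L, NA),
      prob = c(3, 182, 300, 89, 62, 1) / n_ref),
    heavy_bleeding_days_dist = tibble::tibble(
      value = c(0L, 2L, 5L, 8L, 11L),
      prob = c(25, 557, 43, 9, 3) / n_ref),
    cramping_days_dist = tibble::tibble(
      value = c(0, 0.5, 1.5, 3, 4, NA),
      prob = c(12, 212, 296, 61, 54, 2) / n_ref),
    side_effect_probs = c(pain = 591, nausea = 335, fever = 232,
                          diarrhea = 181, chills = 161, vomiting = 89,
                          itchiness = 22, breathing = 1, facial_numbness = 6,
                          sweaty_hands = 4) / n_ref
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Validate a cohort configuration
#'
#' @param cfg a `cohort_config` list.
#' @return `cfg` (classed), or an error naming every offending field.
#' @export
validate_cohort_config <- function(cfg) {
  problems <- character(0)
  note <- function(cond, what) if (cond) problems <<- c(problems, what)
  note(!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 1 ||
         cfg$n != round(cfg$n), "n: must be a positive integer")
  sums_to_one <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)
  for (f in c("site_probs", "duration_probs", "regimen_probs", "age_probs",
              "education_probs", "prior_attempt_probs", "route_probs",
              "source_probs")) {
    note(!sums_to_one(cfg[[f]]), paste0(f, ": probabilities must be >= 0 and sum to 1"))
  }
  for (f in c("expulsion_dist", "bleeding_days_dist", "heavy_bleeding_days_dist",
              "cramping_days_dist")) {
    note(!sums_to_one(cfg[[f]]$prob), paste0(f, ": probs must be >= 0 and sum to 1"))
  }
  for (f in c("selfreport_sensitivity", "selfreport_specificity")) {
    v <- cfg[[f]]
    note(!is.numeric(v) || v <= 0 || v > 1, paste0(f, ": must lie in (0, 1]"))
  }
  note(any(cfg$true_completion_prob < 0 | cfg$true_completion_prob > 1),
       "true_completion_prob: entries must lie in [0, 1]")
  note(any(cfg$fu2_attendance_prob <= 0 | cfg$fu2_attendance_prob > 1),
       "fu2_attendance_prob: must lie in (0, 1]")
  note(cfg$fu1_attendance_prob <= 0 || cfg$fu1_attendance_prob > 1,
       "fu1_attendance_prob: must lie in (0, 1]")
  note(any(cfg$warning_sign_probs < 0 | cfg$warning_sign_probs > 1),
       "warning_sign_probs: entries must lie in [0, 1]")
  note(any(cfg$adverse_event_probs < 0 | cfg$adverse_event_probs > 1),
       "adverse_event_probs: entries must lie in [0, 1]")
  note(any(cfg$care_seeking_prob < 0 | cfg$care_seeking_prob > 1),
       "care_seeking_prob: entries must lie in [0, 1]")
  if (length(problems) > 0) stop("invalid cohort config:\n",
                                 paste(problems, collapse = "\n"))
  class(cfg) <- "cohort_config"
  cfg
}

# substream seed for field k: deterministic, below 2^31
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999983 * k) %% 2147483647L)
}

draw_stream <- function(seed, k, expr_fn) {
  withr_seed(stream_seed(seed, k), expr_fn())
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of observed participant records together with a separate
#' truth table. Given the same configuration (including its `seed`) the
#' output is bit-identical across runs.
#'
#' @param config a [cohort_config()] object.
#' @return list with elements `records` (observed cohort tibble, see
#'   [cohort_dictionary()]) and `truth` (tibble: `participant_id`,
#'   `true_complete`).
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  n <- as.integer(config$n)
  seed <- config$seed
  id <- sprintf("P%05d", seq_len(n))

  site <- draw_stream(seed, 1, function() sample_levels(n, config$site_probs))
  duration <- draw_stream(seed, 2, function() sample_levels(n, config$duration_probs))
  regimen <- draw_stream(seed, 3, function() sample_levels(n, config$regimen_probs))

  p_true <- config$true_completion_prob[cbind(duration, regimen)]
  true_complete <- draw_stream(seed, 4, function() stats::runif(n) < p_true)

  se <- config$selfreport_sensitivity
  sp <- config$selfreport_specificity
  report_complete <- function(u) ifelse(true_complete, u < se, u >= sp)
  rep_fu1 <- draw_stream(seed, 5, function() report_complete(stats::runif(n)))
  rep_fu2 <- draw_stream(seed, 6, function() report_complete(stats::runif(n)))

  fu1_att <- draw_stream(seed, 7, function() stats::runif(n) < config$fu1_attendance_prob)
  p_att2 <- ifelse(true_complete, config$fu2_attendance_prob["complete"],
                   config$fu2_attendance_prob["incomplete"])
  fu2_att <- draw_stream(seed, 8, function() stats::runif(n) < p_att2)

  proc <- draw_stream(seed, 9, function() {
    had <- stats::runif(n) < config$proc_prob
    kind <- ifelse(stats::runif(n) < 0.7, "mva", "dc")
    timing <- ifelse(stats::runif(n) < config$proc_fu1_frac, "fu1", "fu2")
    list(had = had, kind = kind, timing = timing)
  })

  ws <- draw_stream(seed, 10, function() {
    out <- matrix(NA, n, 4, dimnames = list(NULL, warning_sign_fields))
    for (j in 1:4) {
      pj <- ifelse(true_complete, config$warning_sign_probs[j, "complete"],
                   config$warning_sign_probs[j, "incomplete"])
      out[, j] <- stats::runif(n) < pj
    }
    out
  })
  ae <- draw_stream(seed, 11, function() {
    out <- matrix(NA, n, 3, dimnames = list(NULL, adverse_event_fields))
    for (j in 1:3) out[, j] <- stats::runif(n) < config$adverse_event_probs[j]
    out
  })

  any_ws <- rowSums(ws) > 0
  p_care <- ifelse(any_ws, config$care_seeking_prob["warning"],
                   config$care_seeking_prob["none"])
  sought <- draw_stream(seed, 12, function() stats::runif(n) < p_care)

  expul <- draw_stream(seed, 13, function() {
    cat_i <- sample.int(nrow(config$expulsion_dist), n, replace = TRUE,
                        prob = config$expulsion_dist$prob)
    lo <- config$expulsion_dist$lo[cat_i]
    hi <- config$expulsion_dist$hi[cat_i]
    t <- rep(NA_real_, n)
    ok <- !is.na(lo)
    t[ok] <- stats::runif(sum(ok), lo[ok], hi[ok])
    list(category = config$expulsion_dist$category[cat_i], hours = t)
  })

  draw_value_dist <- function(k, dist) {
    draw_stream(seed, k, function() {
      dist$value[sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)]
    })
  }
  bleeding <- draw_value_dist(14, config$bleeding_days_dist)
  heavy <- draw_value_dist(15, config$heavy_bleeding_days_dist)
  cramp <- draw_value_dist(16, config$cramping_days_dist)

  sfx <- draw_stream(seed, 17, function() {
    nm <- names(config$side_effect_probs)
    m <- matrix(stats::runif(n * length(nm)), n) <
      matrix(config$side_effect_probs, n, length(nm), byrow = TRUE)
    out <- apply(m, 1, function(r) paste(nm[r], collapse = ";"))
    ifelse(out == "", "none", out)
  })

  age <- draw_stream(seed, 18, function() sample_levels(n, config$age_probs))
  edu <- draw_stream(seed, 19, function() sample_levels(n, config$education_probs))
  prior <- draw_stream(seed, 20, function() sample_levels(n, config$prior_attempt_probs))
  confirm <- draw_stream(seed, 21, function() sample_levels(n, config$confirm_probs))
  route <- draw_stream(seed, 22, function() sample_levels(n, config$route_probs))
  src <- draw_stream(seed, 23, function() sample_levels(n, config$source_probs))
  fu1_days <- draw_stream(seed, 24, function() sample(7:12, n, replace = TRUE))
  fu2_days <- draw_stream(seed, 25, function() sample(21:26, n, replace = TRUE))
  care_detail <- draw_stream(seed, 26, function() {
    facility <- sample(c("clinic_hospital", "pharmacy_lab", "other"), n,
                       replace = TRUE, prob = c(79, 68, 2) / 149)
    reasons <- ifelse(stats::runif(n) < 0.89, "confirm_completion", "other")
    reasons <- ifelse(any_ws & stats::runif(n) < 0.52,
                      paste(reasons, "symptom_concern", sep = ";"), reasons)
    p_abx <- ifelse(any_ws, 0.409, 0.016)
    treat <- ifelse(stats::runif(n) < p_abx, "antibiotics", "none")
    disclosure <- sample(c("told_nothing", "said_miscarriage", "told_them",
                           "they_found_out", "other"), n, replace = TRUE,
                         prob = c(115, 5, 17, 4, 4) / 145)
    list(facility = facility, reasons = reasons, treat = treat,
         disclosure = disclosure)
  })

  records <- tibble::tibble(
    participant_id = id,
    site = site,
    age_group = age,
    education = ifelse(edu == "missing", NA_character_, edu),
    prior_attempt = ifelse(prior == "missing", NA_character_, prior),
    preg_confirm = confirm,
    duration_weeks = duration,
    regimen = regimen,
    route = route,
    source = src,
    fu1_attended = fu1_att,
    fu1_status = ifelse(fu1_att, ifelse(rep_fu1, "complete",
                                        "not_complete_or_unsure"), NA_character_),
    fu1_days = ifelse(fu1_att, fu1_days, NA_integer_),
    fu2_attended = fu2_att,
    fu2_status = ifelse(fu2_att, ifelse(rep_fu2, "complete",
                                        "not_complete_or_unsure"), NA_character_),
    fu2_days = ifelse(fu2_att, fu2_days, NA_integer_),
    procedural_intervention = ifelse(proc$had, proc$kind, "none"),
    intervention_timing = ifelse(proc$had, proc$timing, NA_character_),
    ws_heavy_bleeding = ws[, 1], ws_unrelieved_pain = ws[, 2],
    ws_fever = ws[, 3], ws_foul_discharge = ws[, 4],
    ae_iv_fluids = ae[, 1], ae_transfusion = ae[, 2], ae_overnight_stay = ae[, 3],
    sought_care = sought,
    care_facility = ifelse(sought, care_detail$facility, NA_character_),
    care_reasons = ifelse(sought, care_detail$reasons, NA_character_),
    care_treatments = ifelse(sought, care_detail$treat, NA_character_),
    disclosure = ifelse(sought, care_detail$disclosure, NA_character_),
    expulsion_observed = ifelse(expul$category == "missing", NA,
                                expul$category != "not_observed"),
    time_to_expulsion_h = expul$hours,
    bleeding_days = as.integer(bleeding),
    heavy_bleeding_days = as.integer(heavy),
    cramping_days = as.numeric(cramp),
    side_effects = sfx
  )
  truth <- tibble::tibble(participant_id = id, true_complete = true_complete)
  list(records = records, truth = truth)
}

#' Write a generated cohort (records + truth) to CSV
#'
#' The truth table goes to a separate `<stem>_truth.csv`; it is never part of
#' the observed record file.
#'
#' @param cohort output of [generate_cohort()].
#' @param path records CSV path.
#' @export
write_generated_cohort <- function(cohort, path) {
  write_cohort(cohort$records, path)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, ".truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE, na = "")
  invisible(path)
}

# -- config file I/O ----------------------------------------------------------

#' Write / read a generator configuration as a structured text file
#'
#' The configuration is stored as YAML key-value maps. Matrix-valued fields
#' are stored with explicit row/column names; distribution tables as column
#' maps. `read_cohort_config()` validates on load.
#'
#' @param cfg a `cohort_config`.
#' @param path file path (conventionally `.yaml`).
#' @export
write_cohort_config <- function(cfg, path) {
  ser <- lapply(unclass(cfg), function(v) {
    if (is.matrix(v)) {
      list(.matrix = TRUE, rows = rownames(v), cols = colnames(v),
           values = as.vector(v))
    } else if (is.data.frame(v)) {
      c(list(.table = TRUE), as.list(v))
    } else if (!is.null(names(v))) {
      as.list(v)            # keep names: serialize as a map, not a sequence
    } else v
  })
  writeLines(yaml::as.yaml(ser, precision = 15), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- lapply(raw, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      matrix(unlist(v$values), nrow = length(v$rows),
             dimnames = list(unlist(v$rows), unlist(v$cols)))
    } else if (is.list(v) && isTRUE(v$.table)) {
      v$.table <- NULL
      cols <- lapply(v, function(col) {
        unlist(lapply(col, function(x) if (is.null(x)) NA else x))
      })
      tibble::as_tibble(cols)
    } else if (is.list(v)) {
      unlist(v)
    } else v
  })
  validate_cohort_config(cfg)
}
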