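# End-to-end pipeline: generate/load -> derive -> tabulate -> test ->
# bias-adjust -> report. Every stage is a thin call into the module
# functions; the pipeline only sequences them and writes files.

#' Pipeline configuration
#'
#' Exactly one of `input_file` (a cohort CSV as written by [write_cohort()])
#' or `generator_config` (a [cohort_config()]) must be supplied.
#'
#' @param input_file path to a cohort CSV, or NULL.
#' @param generator_config a `cohort_config`, or NULL.
#' @param out_dir output directory (created if needed).
#' @param conf_method CI method for endpoints (`"wilson"` or
#'   `"clopper_pearson"`).
#' @param alpha two-sided CI level complement.
#' @param bias_params a [bias_parameters()] object for the QBA stage.
#' @param seed seed for stochastic stages (Monte Carlo Fisher fallback).
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_file = NULL, generator_config = NULL,
                            out_dir = tempfile("misoqba_"),
                            conf_method = "wilson", alpha = 0.05,
                            bias_params = bias_parameters(
                              se_dist = dist_uniform(0.9, 1),
                              sp_dist = dist_uniform(0.75, 1),
                              attend_given_complete = dist_uniform(0.9, 1),
                              attend_given_incomplete = dist_uniform(0.5, 1)),
                            seed = 1L, verbose = FALSE) {
  if (is.null(input_file) == is.null(generator_config)) {
    stop("supply exactly one of input_file or generator_config")
  }
  structure(list(input_file = input_file, generator_config = generator_config,
                 out_dir = out_dir, conf_method = conf_method, alpha = alpha,
                 bias_params = bias_params, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the cohort; validate; derive effectiveness,
#' warning-sign and adverse-event endpoints; write descriptive table analogs
#' (baseline characteristics, effectiveness/safety by duration, physical
#' experience, care seeking by warning-sign status); run the care-seeking
#' chi-square and Fisher tests; run the quantitative bias analysis on the
#' second-follow-up counts; and write a manifest recording the package
#' version, seed, and input checksum. Descriptive stages are deterministic:
#' rerunning the same configuration reproduces their outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the derived objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$input_file)) {
    say("reading cohort: ", config$input_file)
    records <- read_cohort(config$input_file)
    input_md5 <- unname(tools::md5sum(config$input_file))
  } else {
    say("generating synthetic cohort (n=", config$generator_config$n, ")")
    coh <- generate_cohort(config$generator_config)
    records <- coh$records
    write_generated_cohort(coh, out("cohort.csv"))
    input_md5 <- unname(tools::md5sum(out("cohort.csv")))
  }
  validate_cohort(records)

  say("deriving endpoints")
  endpoints <- derive_endpoints(records, conf_method = config$conf_method,
                                alpha = config$alpha)
  utils::write.csv(endpoints, out("endpoints.csv"), row.names = FALSE)

  tables <- list(
    baseline_by_regimen = dplyr::bind_rows(lapply(
      c("site", "age_group", "education", "prior_attempt", "duration_weeks"),
      function(v) dplyr::mutate(
        tabulate_records(records, v, strata = "regimen"), variable = v))),
    effectiveness_last_by_duration = tabulate_records(
      records, "effectiveness_last", strata = "duration_weeks"),
    effectiveness_last_by_regimen = tabulate_records(
      records, "effectiveness_last", strata = "regimen"),
    safety = dplyr::bind_rows(
      dplyr::mutate(tabulate_records(records, "warning_sign"), variable = "warning_sign"),
      dplyr::mutate(tabulate_records(records, "adverse_event"), variable = "adverse_event")),
    care_by_warning = tabulate_records(
      records[records$sought_care %in% TRUE, , drop = FALSE],
      "care_facility", strata = "warning_sign")
  )
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], out(paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  }

  say("contingency tests")
  care_tab <- xtab_from_records(records, "sought_care", "warning_sign")
  tests <- tibble::tibble(
    comparison = "care_seeking_by_warning_sign",
    method = c("chi2", "fisher_exact"),
    statistic = c(chi2_independence(care_tab)$statistic, NA),
    p_value = c(chi2_independence(care_tab)$p_value,
                fisher_exact(care_tab, seed = config$seed)$p_value))
  utils::write.csv(tests, out("tests.csv"), row.names = FALSE)

  say("quantitative bias analysis")
  followed <- records[records$fu2_attended %in% TRUE, , drop = FALSE]
  cls <- classify_effectiveness(followed, "fu2")
  qba <- run_qba(sum(cls == "complete_no_procedure"), nrow(followed),
                 config$bias_params)
  qba_row <- tibble::tibble(
    crude = qba$crude, point_estimate = qba$point_estimate,
    sim_low = qba$sim_low, sim_high = qba$sim_high,
    n_kept = qba$n_kept, n_discarded = qba$n_discarded,
    n_iter = qba$n_iter, seed = qba$seed)
  utils::write.csv(qba_row, out("qba.csv"), row.names = FALSE)

  manifest <- list(
    package = "misoqba",
    version = as.character(utils::packageVersion("misoqba")),
    seed = config$seed, qba_seed = config$bias_params$seed,
    conf_method = config$conf_method, n_records = nrow(records),
    input_md5 = input_md5)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(records = records, endpoints = endpoints, tables = tables,
                 tests = tests, qba = qba,
                 paths = list(out_dir = config$out_dir)))
}
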