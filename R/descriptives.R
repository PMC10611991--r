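# Proportions, binomial confidence intervals, and stratified frequency tables.

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided score interval without continuity correction, i.e. the set of p0
#' not rejected by the score test of H0: p = p0 at level `alpha`:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#' The interval is equivariant under x -> n - x (bounds mirror about 1/2) and
#' its lower bound is exactly 0 when x = 0 (upper exactly 1 when x = n).
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param alpha two-sided type-I error; default 0.05 for a 95% interval.
#' @return numeric vector `c(ci_low, ci_high)`.
#' @examples
#' wilson_interval(625, 637)   # c(0.9665..., 0.9892...)
#' @export
wilson_interval <- function(x, n, alpha = 0.05) {
  stopifnot(length(x) == 1, length(n) == 1)
  if (n < 1) stop("denominator must be >= 1")
  if (x < 0 || x > n) stop("numerator must be in [0, denominator]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lo <- (centre - half) / denom
  hi <- (centre + half) / denom
  if (x == 0) lo <- 0
  if (x == n) hi <- 1
  c(ci_low = max(0, lo), ci_high = min(1, hi))
}

#' Clopper-Pearson exact interval
#'
#' Equal-tailed exact interval from the binomial CDF (via [stats::binom.test()]).
#'
#' @inheritParams wilson_interval
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
clopper_pearson_interval <- function(x, n, alpha = 0.05) {
  stopifnot(n >= 1, x >= 0, x <= n)
  ci <- stats::binom.test(x, n, conf.level = 1 - alpha)$conf.int
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Proportion with confidence interval
#'
#' The package's standard container for a single estimated proportion.
#'
#' @inheritParams wilson_interval
#' @param method `"wilson"` (default) or `"clopper_pearson"`.
#' @return one-row tibble: `numerator`, `denominator`, `proportion`,
#'   `ci_low`, `ci_high`, `alpha`, `method`.
#' @export
endpoint_result <- function(x, n, alpha = 0.05, method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  ci <- switch(method,
    wilson = wilson_interval(x, n, alpha),
    clopper_pearson = clopper_pearson_interval(x, n, alpha))
  tibble::tibble(
    numerator = as.integer(x), denominator = as.integer(n),
    proportion = x / n, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    alpha = alpha, method = method)
}

#' Round half away from zero
#'
#' Published tables round percentages with ties going away from zero
#' (e.g. 0.25 -> 0.3 at one decimal), unlike base [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Stratified frequency table
#'
#' Counts and percentages of a row variable, optionally split by a stratum
#' variable, reproducing the layout of published descriptive tables. The
#' `policy` controls the denominator: `"missing_in_denominator"` keeps rows
#' with a missing value of `row_var` in the column denominator (reported as a
#' `missing` row), `"missing_excluded"` drops them.
#'
#' Either argument may name a raw cohort column or one of the derived
#' classifications `effectiveness_fu1`, `effectiveness_fu2`,
#' `effectiveness_last`, `warning_sign`, `adverse_event`.
#'
#' @param records cohort tibble.
#' @param row_var variable name (character).
#' @param strata optional stratum variable name.
#' @param policy missing-handling policy.
#' @return tibble with `row` (level), `stratum` (`"all"` when unstratified),
#'   `count`, `denominator`, `pct` (percentage rounded to 1 decimal, half away
#'   from zero).
#' @export
tabulate_records <- function(records, row_var, strata = NULL,
                             policy = c("missing_in_denominator", "missing_excluded")) {
  policy <- match.arg(policy)
  v <- derived_or_raw(records, row_var)
  s <- if (is.null(strata)) rep("all", nrow(records)) else
    as.character(derived_or_raw(records, strata))
  if (nrow(records) == 0) {
    return(tibble::tibble(row = character(0), stratum = character(0),
                          count = integer(0), denominator = integer(0),
                          pct = numeric(0)))
  }
  v <- as.character(v)
  if (policy == "missing_in_denominator") {
    v[is.na(v)] <- "missing"
  } else {
    keep <- !is.na(v)
    v <- v[keep]; s <- s[keep]
  }
  keep_s <- !is.na(s)
  v <- v[keep_s]; s <- s[keep_s]
  levels_v <- unique(v)
  out <- lapply(unique(s), function(si) {
    vi <- v[s == si]
    n <- length(vi)
    cnt <- vapply(levels_v, function(l) sum(vi == l), integer(1),
                  USE.NAMES = FALSE)
    tibble::tibble(row = levels_v, stratum = si, count = cnt,
                   denominator = n,
                   pct = round_half_up(100 * cnt / max(n, 1), 1))
  })
  dplyr::bind_rows(out)
}

derived_or_raw <- function(records, var) {
  switch(var,
    effectiveness_fu1  = classify_effectiveness(records, "fu1"),
    effectiveness_fu2  = classify_effectiveness(records, "fu2"),
    effectiveness_last = classify_effectiveness(records, "last_recorded"),
    warning_sign  = ifelse(composite_warning_sign(records), "warning_sign", "none"),
    adverse_event = ifelse(composite_adverse_event(records), "adverse_event", "none"),
    {
      if (!var %in% names(records)) stop("unknown variable: ", var)
      records[[var]]
    })
}

#' Proportion of the cohort expelling within a time window
#'
#' Numerator: participants with an observed expulsion time at or under
#' `hours` after the first dose. Denominator: the full cohort; participants
#' who did not notice products of conception (or with missing expulsion data)
#' count as not-within.
#'
#' @param records cohort tibble.
#' @param hours window length in hours (> 0).
#' @param ... passed to [endpoint_result()].
#' @return one-row tibble as from [endpoint_result()].
#' @export
proportion_expelled_within <- function(records, hours = 24, ...) {
  stopifnot(hours > 0)
  num <- sum(records$expulsion_observed %in% TRUE &
               !is.na(records$time_to_expulsion_h) &
               records$time_to_expulsion_h <= hours)
  endpoint_result(num, nrow(records), ...)
}

#' Render a frequency table as aligned plain text
#'
#' @param tab output of [tabulate_records()].
#' @param title optional heading line.
#' @return character scalar.
#' @export
format_frequency_table <- function(tab, title = NULL) {
  wide <- tab
  wide$cell <- sprintf("%d (%.1f)", wide$count, wide$pct)
  strata <- unique(wide$stratum)
  rows <- unique(wide$row)
  m <- matrix("0 (0.0)", nrow = length(rows), ncol = length(strata),
              dimnames = list(rows, strata))
  for (i in seq_len(nrow(wide))) m[wide$row[i], wide$stratum[i]] <- wide$cell[i]
  header <- c("", strata)
  body <- cbind(rows, m)
  widths <- pmax(nchar(header), apply(nchar(body), 2, max))
  fmt_row <- function(r) paste(mapply(formatC, r, width = widths), collapse = "  ")
  lines <- c(if (!is.null(title)) title, fmt_row(header),
             apply(body, 1, fmt_row))
  paste(lines, collapse = "\n")
}
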