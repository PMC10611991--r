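# Contingency-table tests for group comparisons.
#
# Both tests operate on labeled r x c count matrices built with
# contingency_table(). Missing categories are expected to be dropped by the
# caller before testing (the published comparisons exclude missing values);
# xtab_from_records() does this.

#' Build a labeled contingency table
#'
#' @param counts r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param row_labels,col_labels optional dimension labels.
#' @return an integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2 x 2")
  if (any(m < 0) || any(is.na(m))) stop("counts must be nonnegative")
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integers")
  if (sum(m) < 1) stop("table total must be >= 1")
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  class(m) <- c("contingency_table", class(m))
  m
}

#' Cross-tabulate two cohort variables for testing
#'
#' Builds the r x c table of two (raw or derived) variables, dropping
#' participants with a missing value of either — the convention used for the
#' published between-group comparisons.
#'
#' @param records cohort tibble.
#' @param var1,var2 variable names as accepted by [tabulate_records()].
#' @return a `contingency_table`.
#' @export
xtab_from_records <- function(records, var1, var2) {
  a <- as.character(derived_or_raw(records, var1))
  b <- as.character(derived_or_raw(records, var2))
  keep <- !is.na(a) & !is.na(b)
  tab <- table(a[keep], b[keep])
  contingency_table(unclass(tab), rownames(tab), colnames(tab))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without Yates continuity correction (the correction is
#' available via `correct = TRUE`), df = (r-1)(c-1), upper-tail p-value.
#'
#' @param table a `contingency_table` or plain count matrix.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return list of class `miso_test`: `method`, `statistic`, `df`, `p_value`.
#' @export
chi2_independence <- function(table, correct = FALSE) {
  m <- unclass_table(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square test undefined: zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(method = "chi2", statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = unname(ht$p.value),
                 n_mc = NULL, seed = NULL),
            class = "miso_test")
}

#' Fisher exact test
#'
#' For 2 x 2 tables: the exact two-sided p-value by probability ordering (the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table). For larger tables: the exact network algorithm when the table
#' total is at most `mc_threshold`, otherwise a Monte Carlo p-value with
#' `n_mc` simulated tables under a recorded seed.
#'
#' @param table a `contingency_table` or plain count matrix.
#' @param mc_threshold table total above which r x c tables fall back to
#'   Monte Carlo (default 10000; ignored for 2 x 2, which is always exact).
#' @param n_mc Monte Carlo replicates (default 1e6).
#' @param seed RNG seed for the Monte Carlo fallback.
#' @return list of class `miso_test`: `method` (`fisher_exact` or
#'   `fisher_mc`), `p_value`, and for Monte Carlo runs `n_mc` and `seed`.
#' @export
fisher_exact <- function(table, mc_threshold = 10000, n_mc = 1e6, seed = 1L) {
  m <- unclass_table(table)
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integers")
  two_by_two <- nrow(m) == 2 && ncol(m) == 2
  if (two_by_two || sum(m) <= mc_threshold) {
    ht <- stats::fisher.test(m)
    structure(list(method = "fisher_exact", statistic = NULL, df = NULL,
                   p_value = unname(ht$p.value), n_mc = NULL, seed = NULL),
              class = "miso_test")
  } else {
    p <- withr_seed(seed, {
      stats::fisher.test(m, simulate.p.value = TRUE, B = n_mc)$p.value
    })
    structure(list(method = "fisher_mc", statistic = NULL, df = NULL,
                   p_value = unname(p), n_mc = as.integer(n_mc),
                   seed = as.integer(seed)),
              class = "miso_test")
  }
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

unclass_table <- function(table) {
  m <- as.matrix(table)
  class(m) <- "matrix"
  storage.mode(m) <- "double"
  m
}

#' @export
print.miso_test <- function(x, ...) {
  cat(x$method,
      if (!is.null(x$statistic)) sprintf(" statistic=%.4f df=%d", x$statistic, x$df),
      sprintf(" p=%.4g", x$p_value),
      if (!is.null(x$n_mc)) sprintf(" (n_mc=%d, seed=%d)", x$n_mc, x$seed),
      "\n", sep = "")
  invisible(x)
}
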