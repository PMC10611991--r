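# Monte Carlo quantitative bias analysis (QBA) for the crude effectiveness
# proportion. Two bias mechanisms are modeled:
#
#   (1) outcome misclassification: the primary outcome is self-reported, with
#       sensitivity Se = P(report complete | truly complete) and specificity
#       Sp = P(report not complete/unsure | truly not complete);
#   (2) selection from differential loss to follow-up: attendance at the
#       final follow-up may depend on the true outcome.
#
# The analysis is summary-level: each iteration draws bias parameters from
# their prior distributions, inverts the misclassification on the observed
# count, reweights by inverse attendance probabilities, and adds binomial
# sampling error, yielding a distribution of bias-adjusted proportions whose
# median and 2.5th/97.5th percentiles form the adjusted estimate and 95%
# simulation interval.

# -- prior distribution specs -------------------------------------------------

#' Bias-parameter prior distributions
#'
#' Constructors for the distribution families accepted by
#' [bias_parameters()]: a point mass, a uniform, a beta, or a trapezoidal
#' density (flat between two modes with linear shoulders). Supports must lie
#' within (0, 1].
#'
#' @param value point-mass location.
#' @param min,max support endpoints.
#' @param shape1,shape2 beta shape parameters.
#' @param mode_lo,mode_hi endpoints of the trapezoid's flat top.
#' @return an object of class `qba_dist`.
#' @name qba_dist
NULL

#' @rdname qba_dist
#' @export
dist_point <- function(value) {
  check_unit_support(value, value, "point")
  structure(list(family = "point", value = value), class = "qba_dist")
}

#' @rdname qba_dist
#' @export
dist_uniform <- function(min, max) {
  if (min > max) stop("uniform: min > max")
  check_unit_support(min, max, "uniform")
  structure(list(family = "uniform", min = min, max = max), class = "qba_dist")
}

#' @rdname qba_dist
#' @export
dist_beta <- function(shape1, shape2) {
  if (shape1 <= 0 || shape2 <= 0) stop("beta: shapes must be positive")
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "qba_dist")
}

#' @rdname qba_dist
#' @export
dist_trapezoidal <- function(min, mode_lo, mode_hi, max) {
  if (!(min <= mode_lo && mode_lo <= mode_hi && mode_hi <= max)) {
    stop("trapezoidal: need min <= mode_lo <= mode_hi <= max")
  }
  if (min == max) return(dist_point(min))
  check_unit_support(min, max, "trapezoidal")
  structure(list(family = "trapezoidal", min = min, mode_lo = mode_lo,
                 mode_hi = mode_hi, max = max), class = "qba_dist")
}

check_unit_support <- function(lo, hi, family) {
  if (lo <= 0 || hi > 1) {
    stop(family, ": support must lie within (0, 1]")
  }
  invisible(TRUE)
}

#' Draw from a bias-parameter prior
#'
#' @param dist a `qba_dist`.
#' @param n number of draws.
#' @return numeric vector of length `n`. Draws use the current RNG stream.
#' @export
draw_dist <- function(dist, n) {
  stopifnot(inherits(dist, "qba_dist"))
  switch(dist$family,
    point = rep(dist$value, n),
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    trapezoidal = rtrapezoid(n, dist$min, dist$mode_lo, dist$mode_hi, dist$max))
}

# inverse-CDF sampler for the trapezoidal density on [a,d] flat on [b,c]
rtrapezoid <- function(n, a, b, c, d) {
  u <- stats::runif(n)
  h <- 2 / (d + c - a - b)           # height of the flat section
  a1 <- h * (b - a) / 2              # mass of the rising shoulder
  a2 <- h * (c - b)                  # mass of the flat top
  x <- numeric(n)
  lo <- u < a1
  mid <- !lo & u < a1 + a2
  hi <- !lo & !mid
  if (any(lo))  x[lo]  <- a + sqrt(2 * u[lo] * (b - a) / h)
  if (any(mid)) x[mid] <- b + (u[mid] - a1) / h
  if (any(hi))  x[hi]  <- d - sqrt(2 * (1 - u[hi]) * (d - c) / h)
  x
}

# -- parameter container ------------------------------------------------------

#' Bias parameters for the quantitative bias analysis
#'
#' @param se_dist,sp_dist priors for self-report sensitivity and specificity.
#' @param attend_given_complete,attend_given_incomplete priors for the
#'   probability of attending the final follow-up, by true outcome.
#' @param n_iter Monte Carlo iterations (default 50000).
#' @param seed RNG seed for the run.
#' @param impossible_draw_policy what to do with draws whose corrected
#'   proportion falls outside [0, 1]: `"discard"` (default; tallied) or
#'   `"truncate"` (clamped to the boundary).
#' @return list of class `bias_parameters`.
#' @export
bias_parameters <- function(se_dist = dist_point(1), sp_dist = dist_point(1),
                            attend_given_complete = dist_point(1),
                            attend_given_incomplete = dist_point(1),
                            n_iter = 50000L, seed = 1L,
                            impossible_draw_policy = c("discard", "truncate")) {
  for (d in list(se_dist, sp_dist, attend_given_complete, attend_given_incomplete)) {
    if (!inherits(d, "qba_dist")) stop("distributions must be qba_dist objects")
  }
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(
    se_dist = se_dist, sp_dist = sp_dist,
    attend_given_complete = attend_given_complete,
    attend_given_incomplete = attend_given_incomplete,
    n_iter = as.integer(n_iter), seed = as.integer(seed),
    impossible_draw_policy = match.arg(impossible_draw_policy)),
    class = "bias_parameters")
}

# -- the corrections ----------------------------------------------------------

#' Misclassification correction of a proportion
#'
#' Inverts the standard 2 x 2 misclassification model: with observed
#' proportion p_obs and classifier sensitivity `se` and specificity `sp`,
#' the corrected true proportion is
#' \deqn{p = \frac{p_{obs} - (1 - sp)}{se + sp - 1}.}
#' A result outside [0, 1] signals that the (se, sp) pair is incompatible
#' with the observed data; it is returned as-is for the caller's
#' impossible-draw policy to handle.
#'
#' @param observed_pos observed positive count.
#' @param n denominator.
#' @param se,sp sensitivity and specificity (vectors allowed); requires
#'   `se + sp > 1` (an informative classifier).
#' @return corrected proportion(s); may fall outside [0, 1].
#' @export
misclassification_correct <- function(observed_pos, n, se, sp) {
  if (observed_pos < 0 || observed_pos > n) stop("observed_pos must be in [0, n]")
  if (any(se + sp <= 1)) stop("se + sp must exceed 1")
  p_obs <- observed_pos / n
  (p_obs - (1 - sp)) / (se + sp - 1)
}

#' Selection adjustment by inverse probability of attendance
#'
#' Reweights the followed participants by the inverse of their (true-outcome
#' specific) probability of attending follow-up, recovering the full-cohort
#' proportion when attendance depends only on the true outcome.
#'
#' @param n_complete,n_incomplete counts among followed participants by
#'   (corrected) outcome class. Non-integer pseudo-counts are accepted.
#' @param attend_complete,attend_incomplete attendance probabilities in
#'   (0, 1] (vectors allowed).
#' @return adjusted proportion(s) complete.
#' @export
selection_adjust <- function(n_complete, n_incomplete,
                             attend_complete, attend_incomplete) {
  if (any(attend_complete <= 0) || any(attend_incomplete <= 0)) {
    stop("attendance probabilities must be > 0")
  }
  if (any(n_complete < 0) || any(n_incomplete < 0)) stop("counts must be >= 0")
  wc <- n_complete / attend_complete
  wi <- n_incomplete / attend_incomplete
  ifelse(wc + wi == 0, NaN, wc / (wc + wi))
}

# -- the Monte Carlo engine ---------------------------------------------------

#' Run the quantitative bias analysis
#'
#' Per iteration: draw (se, sp, attendance probabilities) from their priors;
#' invert the misclassification on the observed completion count among
#' followed participants; apply the inverse-probability-of-attendance
#' selection adjustment; then add random (sampling) error by drawing the
#' final count from a binomial at the adjusted proportion. Draws with
#' `se + sp <= 1` or with a corrected proportion outside [0, 1] are handled
#' by the impossible-draw policy (discarded and tallied by default).
#'
#' @param observed_complete observed count complete-without-intervention
#'   among followed participants.
#' @param n_followed number of followed participants.
#' @param params a [bias_parameters()] object.
#' @param point_statistic summary used as the adjusted point estimate:
#'   `"median"` (default) or `"mean"`.
#' @param keep_trace retain the per-iteration draws and adjusted proportions.
#' @return list of class `qba_result`: `point_estimate`, `sim_low`,
#'   `sim_high` (2.5th/97.5th percentiles), `n_kept`, `n_discarded`,
#'   `n_iter`, `seed`, `crude`, and optionally `trace` (a tibble).
#' @export
run_qba <- function(observed_complete, n_followed, params,
                    point_statistic = c("median", "mean"),
                    keep_trace = FALSE) {
  stopifnot(inherits(params, "bias_parameters"))
  point_statistic <- match.arg(point_statistic)
  if (n_followed < 1) stop("n_followed must be >= 1")
  if (observed_complete < 0 || observed_complete > n_followed) {
    stop("observed_complete must be in [0, n_followed]")
  }
  n_iter <- params$n_iter
  p_obs <- observed_complete / n_followed

  res <- withr_seed(params$seed, {
    se <- draw_dist(params$se_dist, n_iter)
    sp <- draw_dist(params$sp_dist, n_iter)
    ac <- draw_dist(params$attend_given_complete, n_iter)
    ai <- draw_dist(params$attend_given_incomplete, n_iter)

    informative <- se + sp > 1
    p_corr <- rep(NA_real_, n_iter)
    p_corr[informative] <- (p_obs - (1 - sp[informative])) /
      (se[informative] + sp[informative] - 1)

    in_range <- informative & p_corr >= 0 & p_corr <= 1
    if (params$impossible_draw_policy == "truncate") {
      keep <- informative
      p_corr[keep] <- pmin(1, pmax(0, p_corr[keep]))
    } else {
      keep <- in_range
    }
    if (!any(keep)) {
      stop("all ", n_iter, " draws were impossible: the (se, sp) prior region ",
           "is incompatible with observed proportion ", signif(p_obs, 4))
    }

    p_sel <- rep(NA_real_, n_iter)
    p_sel[keep] <- selection_adjust(
      p_corr[keep] * n_followed, (1 - p_corr[keep]) * n_followed,
      ac[keep], ai[keep])

    p_final <- rep(NA_real_, n_iter)
    p_final[keep] <- stats::rbinom(sum(keep), n_followed, p_sel[keep]) / n_followed

    list(se = se, sp = sp, ac = ac, ai = ai, p_corr = p_corr,
         p_sel = p_sel, p_final = p_final, keep = keep)
  })

  kept <- res$p_final[res$keep]
  q <- stats::quantile(kept, c(0.025, 0.975), names = FALSE)
  out <- list(
    point_estimate = if (point_statistic == "median") stats::median(kept) else mean(kept),
    sim_low = q[1], sim_high = q[2],
    n_kept = sum(res$keep), n_discarded = as.integer(n_iter - sum(res$keep)),
    n_iter = n_iter, seed = params$seed, crude = p_obs,
    point_statistic = point_statistic)
  if (keep_trace) {
    out$trace <- tibble::tibble(
      iter = seq_len(n_iter), se = res$se, sp = res$sp,
      attend_complete = res$ac, attend_incomplete = res$ai,
      p_corrected = res$p_corr, p_selection_adjusted = res$p_sel,
      p_final = res$p_final, kept = res$keep)
  }
  class(out) <- "qba_result"
  out
}

#' @export
print.qba_result <- function(x, ...) {
  cat(sprintf(
    "bias-adjusted estimate (%s): %.1f%% (95%% simulation interval %.1f%%-%.1f%%)\n",
    x$point_statistic, 100 * x$point_estimate, 100 * x$sim_low, 100 * x$sim_high))
  cat(sprintf("crude: %.1f%%; iterations kept %d of %d (seed %d)\n",
              100 * x$crude, x$n_kept, x$n_iter, x$seed))
  invisible(x)
}
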