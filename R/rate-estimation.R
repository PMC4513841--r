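#' Cell divisions per culture from titer counts
#'
#' The divisor of the null-class estimator is the number of cell divisions
#' a culture has undergone, `Nt - N0`. Final CFU per well (Nt) is measured
#' on a subset of titer wells and averaged.
#'
#' @param titer_final_counts Final CFU of each titer well (all >= `initial_cells`).
#' @param initial_cells Inoculum CFU per well (N0).
#' @return Divisions per culture, rounded to the nearest integer.
#' @examples
#' total_divisions(c(9e7, 1.1e8), initial_cells = 1e2)
#' @export
total_divisions <- function(titer_final_counts, initial_cells) {
  if (!is.numeric(titer_final_counts) || length(titer_final_counts) < 1L) {
    abort("`titer_final_counts` must be a non-empty numeric vector.")
  }
  initial_cells <- check_count(initial_cells, "initial_cells", min = 1L)
  if (any(titer_final_counts < initial_cells)) {
    abort("every final count must be >= `initial_cells`.")
  }
  round(mean(titer_final_counts) - initial_cells)
}

#' Null-class (p0) fluctuation-test mutation-rate estimate
#'
#' Estimates the per-division mutation rate from the fraction of parallel
#' cultures containing no mutant: the expected number of mutations per
#' culture is `m = -ln(p0)` with `p0 = n_negative / n_total`, and the rate
#' is `m` divided by the number of cell divisions. Under the default
#' `per_culture` convention the divisor is the divisions of ONE culture
#' (`d = Nt - N0`); the `summed` convention divides additionally by
#' `n_total`, i.e. uses the divisions summed over all cultures.
#'
#' Confidence intervals are exact Clopper-Pearson intervals for `p0`
#' mapped through the decreasing transform `-ln(.) / d` (so the upper
#' `p0` limit gives the lower rate limit).
#'
#' Boundary cases return bounds rather than infinities: with
#' `n_negative = 0` the point estimate is infinite and only a finite lower
#' rate bound is reported (from the one-sided Clopper-Pearson upper limit
#' of `p0`); with `n_negative = n_total` the point estimate is 0 with a
#' one-sided upper rate bound.
#'
#' @param n_negative Number of cultures with no mutant (negative wells).
#' @param n_total Total number of scored cultures.
#' @param divisions Cell divisions per culture (`d = Nt - N0`).
#' @param ci_level Confidence level (default 0.95).
#' @param convention `"per_culture"` (default) or `"summed"`.
#' @return A `p0_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' p0_estimate(37, 100, divisions = 1e10)   # -ln(0.37)/1e10
#' p0_estimate(50, 100, divisions = 1e8)    # ln(2)/1e8
#' @export
p0_estimate <- function(n_negative, n_total, divisions, ci_level = 0.95,
                        convention = c("per_culture", "summed")) {
  n_negative <- check_count(n_negative, "n_negative")
  n_total <- check_count(n_total, "n_total", min = 1L)
  if (n_negative > n_total) abort("`n_negative` cannot exceed `n_total`.")
  divisions <- check_count(divisions, "divisions", min = 1L)
  ci_level <- check_prob(ci_level, "ci_level")
  convention <- match.arg(convention)
  denom <- if (convention == "summed") divisions * n_total else divisions

  alpha <- 1 - ci_level
  x <- n_negative
  n <- n_total
  if (x == 0) {
    # no negative wells: only a lower rate bound is identifiable
    p_hi <- qbeta(1 - alpha, x + 1, n - x)  # one-sided CP upper limit of p0
    point <- Inf
    ci <- c(-log(p_hi) / denom, Inf)
  } else if (x == n) {
    # all wells negative: rate point 0 with a one-sided upper bound
    p_lo <- qbeta(alpha, x, n - x + 1)      # one-sided CP lower limit of p0
    point <- 0
    ci <- c(0, -log(p_lo) / denom)
  } else {
    p0 <- x / n
    p_lo <- qbeta(alpha / 2, x, n - x + 1)
    p_hi <- qbeta(1 - alpha / 2, x + 1, n - x)
    point <- -log(p0) / denom
    ci <- c(-log(p_hi) / denom, -log(p_lo) / denom)
  }
  structure(
    list(point = point, ci_low = ci[[1]], ci_high = ci[[2]],
         ci_level = ci_level, convention = convention,
         n_negative = n_negative, n_total = n_total, divisions = divisions),
    class = "p0_fit"
  )
}

#' Estimate a mutation rate from simulated or recorded well outcomes
#'
#' Tidy front end to [p0_estimate()]: takes a well-outcome table as
#' produced by [simulate_fluctuation_experiment()] (or read with
#' [read_well_csv()]), counts negative selective wells, derives divisions
#' per culture from the titer wells via [total_divisions()], and fits.
#'
#' @param wells Data frame with columns `arm`, `outcome`, `final_cfu`.
#' @param initial_cells Inoculum CFU per well (N0).
#' @param divisions Divisions per culture; derived from titer wells when
#'   `NULL`.
#' @inheritParams p0_estimate
#' @return A `p0_fit` object.
#' @examples
#' wells <- simulate_fluctuation_experiment(
#'   fluctuation_design(culture_model = culture_model(1e2, 1e8, 1e-8)),
#'   seed = 7)
#' estimate_rate(wells, initial_cells = 1e2)
#' @export
estimate_rate <- function(wells, initial_cells, divisions = NULL,
                          ci_level = 0.95,
                          convention = c("per_culture", "summed")) {
  wells <- as_tibble(wells)
  if (!all(c("arm", "outcome") %in% names(wells))) {
    abort("`wells` needs columns `arm` and `outcome`.")
  }
  sel <- dplyr::filter(wells, .data$arm == "selective")
  if (nrow(sel) == 0L) abort("no selective wells in `wells`.")
  if (is.null(divisions)) {
    titer <- dplyr::filter(wells, .data$arm == "titer")
    if (nrow(titer) == 0L || !"final_cfu" %in% names(wells)) {
      abort("no titer wells; supply `divisions` explicitly.")
    }
    divisions <- total_divisions(titer$final_cfu, initial_cells)
  }
  p0_estimate(sum(sel$outcome == "negative"), nrow(sel), divisions,
              ci_level = ci_level, convention = convention)
}

#' @export
print.p0_fit <- function(x, ...) {
  cat("Null-class (p0) fluctuation-test estimate\n")
  cat(sprintf("  negative wells: %g / %g; divisions per culture: %g\n",
              x$n_negative, x$n_total, x$divisions))
  cat(sprintf("  rate: %.4g per division [%0.4g, %0.4g] (%g%% CI, %s)\n",
              x$point, x$ci_low, x$ci_high, 100 * x$ci_level,
              x$convention))
  invisible(x)
}

#' @describeIn p0_estimate One-row tibble with `estimate`, `conf.low`,
#'   `conf.high`.
#' @param x A `p0_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.p0_fit <- function(x, ...) {
  tibble(term = "mutation_rate", estimate = x$point,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @describeIn p0_estimate One-row tibble of fit inputs and settings.
#' @exportS3Method generics::glance
glance.p0_fit <- function(x, ...) {
  tibble(n_negative = x$n_negative, n_total = x$n_total,
         p0 = x$n_negative / x$n_total, divisions = x$divisions,
         ci_level = x$ci_level, convention = x$convention)
}

#' Fold ratio between two rates or frequencies
#'
#' @param a,b Non-negative rates on the same scale; `b > 0`.
#' @return `a / b`.
#' @examples
#' fold_ratio(1.42e-8, 1.11e-10)  # ~128-fold
#' @export
fold_ratio <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L ||
      length(b) != 1L || a < 0 || b < 0) {
    abort("`a` and `b` must be single non-negative numbers.")
  }
  if (b == 0) abort("`b` must be > 0.")
  a / b
}
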