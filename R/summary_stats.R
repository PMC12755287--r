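# Prevalence estimation, Wilson score intervals, exact binomial enrichment
# tests and fold-elevation ratios.

#' Wilson score confidence interval for a binomial proportion
#'
#' The score-test inversion interval: with \code{phat = k/n} and normal
#' quantile \code{z},
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}.}
#' Unlike the Wald interval it never leaves [0, 1] and behaves sensibly at
#' k = 0 or k = n. The quantile is computed exactly for the requested level
#' rather than hard-coding 1.96.
#'
#' @param k Success count(s), \code{0 <= k <= n}.
#' @param n Denominator(s), \code{n >= 1}.
#' @param conf Two-sided confidence level, default 0.95.
#' @return A matrix with columns \code{low} and \code{high} (one row per
#'   input; a single row is still a matrix).
#' @examples
#' round(wilson_ci(30, 77) * 100, 1)  # 28.8 50.1
#' round(wilson_ci(10, 52) * 100, 1)  # 10.8 31.9
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  centre <- phat + z^2 / (2 * n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  cbind(low = pmax(0, (centre - half) / denom),
        high = pmin(1, (centre + half) / denom))
}

#' Proportion with Wilson interval
#'
#' Convenience wrapper bundling a count, denominator, proportion and 95
#' percent Wilson bounds, the unit in which all pattern and component
#' prevalences are reported.
#'
#' @inheritParams wilson_ci
#' @return A data frame with columns \code{k}, \code{n}, \code{proportion},
#'   \code{ci_low}, \code{ci_high}.
#' @export
prevalence <- function(k, n, conf = 0.95) {
  ci <- wilson_ci(k, n, conf)
  data.frame(k = k, n = n, proportion = k / n,
             ci_low = ci[, "low"], ci_high = ci[, "high"])
}

#' Exact binomial test of an observed count against a reference proportion
#'
#' Two-sided exact p-value for \code{k} successes in \code{n} trials under a
#' null proportion \code{p0}, using the minimum-likelihood rule (sum of all
#' binomial point probabilities not exceeding the observed one), the
#' convention of \code{stats::binom.test}, which performs the computation. A
#' one-sided alternative is available.
#'
#' @inheritParams wilson_ci
#' @param p0 Null proportion. The degenerate values 0 and 1 are handled
#'   directly: the p-value is 1 when the observed count is the only possible
#'   one (k = 0 under p0 = 0, k = n under p0 = 1) and 0 otherwise.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return The exact p-value.
#' @examples
#' exact_binomial_p(1, 10, 0.5)  # ~0.0215
#' @export
exact_binomial_p <- function(k, n, p0,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (k < 0 || k > n || n < 1) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]", call. = FALSE)
  if (p0 == 0) return(if (k == 0) 1 else 0)
  if (p0 == 1) return(if (k == n) 1 else 0)
  stats::binom.test(k, n, p = p0, alternative = alternative)$p.value
}

#' Fold elevation of an observed prevalence over a reference
#'
#' The ratio \code{observed / expected}. The display variant first rounds
#' both proportions to one decimal place on the percentage scale and then
#' forms the ratio rounded to one decimal — the convention used when quoting
#' headline elevations from printed percentages (39.0\% over 1.4\% gives
#' 27.9-fold), which can differ slightly from the unrounded ratio.
#'
#' @param observed Observed proportion (in [0, 1], or a percentage if both
#'   arguments use the same scale).
#' @param expected Reference proportion, must be positive.
#' @param display If TRUE, apply the printed-percentage rounding convention.
#' @return The fold elevation (one decimal when \code{display = TRUE}).
#' @examples
#' fold_elevation(0.390, 0.014, display = TRUE)   # 27.9
#' fold_elevation(0.468, 0.109, display = TRUE)   # 4.3
#' @export
fold_elevation <- function(observed, expected, display = FALSE) {
  if (any(expected <= 0)) {
    stop("expected proportion must be positive", call. = FALSE)
  }
  if (any(observed < 0)) {
    stop("observed proportion must be non-negative", call. = FALSE)
  }
  if (display) {
    round(round(100 * observed, 1) / round(100 * expected, 1), 1)
  } else {
    observed / expected
  }
}

#' Enrichment of an observed prevalence relative to a simulated expectation
#'
#' Combines the observed prevalence (with Wilson interval), the exact
#' binomial test against the reference proportion, and both the raw and
#' display fold elevations.
#'
#' @inheritParams wilson_ci
#' @param p0 Reference (null-expectation) proportion in (0, 1).
#' @return A list with \code{observed} (a [prevalence()] row),
#'   \code{expected_p0}, \code{fold}, \code{fold_display}, \code{binom_p}.
#' @examples
#' enrichment(30, 77, 0.014)
#' @export
enrichment <- function(k, n, p0, conf = 0.95) {
  obs <- prevalence(k, n, conf)
  list(
    observed = obs,
    expected_p0 = p0,
    fold = fold_elevation(obs$proportion, p0),
    fold_display = fold_elevation(obs$proportion, p0, display = TRUE),
    binom_p = exact_binomial_p(k, n, p0)
  )
}
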