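# Fast scalar/vector p-value kernels. These are deliberately plain-numeric
# (no table2x2 dispatch) because the fragility search evaluates them once per
# candidate event split, up to n_mod + 1 times per trial.

# Two-sided Fisher exact p by hypergeometric enumeration with the
# minimum-likelihood rule: sum the point probabilities of every table sharing
# the observed margins whose probability does not exceed that of the observed
# table. The relative tolerance on the comparison matches the one
# stats::fisher.test uses, so the two agree to machine precision.
.fisher_p <- function(a, b, c, d) {
  m <- a + c                       # event-column margin
  n1 <- a + b
  N <- n1 + c + d
  if (m == 0L || m == N) {
    return(1)                      # degenerate column margin: only one table
  }
  lo <- max(0L, m - (c + d))
  hi <- min(m, n1)
  logp <- stats::dhyper(lo:hi, m, N - m, n1, log = TRUE)
  p_obs <- logp[a - lo + 1L]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

# Pearson chi-square on 1 df without continuity correction, vectorised over
# cells. Degenerate margins (an all-zero row or column) give NA.
.pearson_stat <- function(a, b, c, d) {
  N <- a + b + c + d
  denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  stat <- N * (as.numeric(a) * d - as.numeric(b) * c)^2 / denom
  stat[denom == 0] <- NA_real_
  stat
}

.pearson_p <- function(a, b, c, d) {
  stats::pchisq(.pearson_stat(a, b, c, d), df = 1L, lower.tail = FALSE)
}

# Test-selection rule, vectorised. TRUE where Fisher's exact test applies.
#  * simulation: Fisher iff N <= 50 or any cell < 5
#  * empirical:  Pearson iff N > 5000 and every cell >= 50, else Fisher
.use_fisher <- function(N, min_cell, context) {
  if (context == "simulation") {
    N <= 50L | min_cell < 5L
  } else {
    !(N > 5000L & min_cell >= 50L)
  }
}

.match_context <- function(context) {
  match.arg(context, c("empirical", "simulation"))
}

# Significance comparison with an absolute guard of 1e-9: a discrete p-value
# that is exactly alpha (ties count as significant) can land a few ulps on
# either side depending on the summation route; the guard is far below the
# spacing of achievable p-values near 0.05 at any realistic sample size.
.is_sig <- function(p, alpha = 0.05) {
  p <= alpha + 1e-9
}

.new_test_result <- function(p, test_used, alpha, degenerate = FALSE) {
  structure(
    list(p_value = p, test_used = test_used,
         significant = .is_sig(p, alpha), alpha = alpha,
         degenerate = degenerate),
    class = "pfrnb_test"
  )
}

#' @export
print.pfrnb_test <- function(x, ...) {
  cat(sprintf("%s: p = %.5g (%s at alpha = %g)%s\n",
              switch(x$test_used,
                     fisher_exact = "Fisher's exact test (two-sided)",
                     pearson_chisq = "Pearson chi-square (1 df, uncorrected)"),
              x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha,
              if (isTRUE(x$degenerate)) " [degenerate margins]" else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates every table consistent with the observed margins and sums the
#' hypergeometric point probabilities that do not exceed the observed table's
#' probability (the minimum-likelihood two-sided rule, the convention used by
#' \code{stats::fisher.test}). Tables with a zero event or non-event margin
#' admit only one configuration and return p = 1 with a degeneracy flag.
#'
#' @param x A \code{table2x2} (or anything [as_table2x2()] accepts).
#' @param alpha Significance level used for the \code{significant} flag.
#'   Fixed at 0.05 everywhere the package classifies evidence patterns; the
#'   argument exists for exploratory use only.
#' @return A \code{pfrnb_test}: list with \code{p_value}, \code{test_used},
#'   \code{significant}, \code{alpha}, \code{degenerate}.
#' @examples
#' fisher_exact(table2x2(1, 9, 9, 1))    # p ~ 0.00109
#' fisher_exact(table2x2(0, 10, 5, 5))   # p ~ 0.0325
#' @export
fisher_exact <- function(x, alpha = 0.05) {
  x <- as_table2x2(x)
  degen <- (x$a + x$c) == 0L || (x$b + x$d) == 0L
  p <- .fisher_p(x$a, x$b, x$c, x$d)
  .new_test_result(p, "fisher_exact", alpha, degenerate = degen)
}

#' Pearson chi-square test for a 2x2 table
#'
#' The standard one-degree-of-freedom Pearson statistic without continuity
#' correction, with the p-value from the upper chi-square tail. A table whose
#' event (or non-event) margin is zero has expected counts of zero; such
#' tables are returned as degenerate with p = 1 rather than an error so that
#' the fragility search can traverse them.
#'
#' @inheritParams fisher_exact
#' @return A \code{pfrnb_test} with an extra \code{statistic} element.
#' @examples
#' pearson_chisq(table2x2(60, 40, 40, 60))  # statistic 8, p ~ 0.00468
#' @export
pearson_chisq <- function(x, alpha = 0.05) {
  x <- as_table2x2(x)
  stat <- .pearson_stat(x$a, x$b, x$c, x$d)
  if (is.na(stat)) {
    res <- .new_test_result(1, "pearson_chisq", alpha, degenerate = TRUE)
    res$statistic <- NA_real_
    return(res)
  }
  res <- .new_test_result(stats::pchisq(stat, 1L, lower.tail = FALSE),
                          "pearson_chisq", alpha)
  res$statistic <- stat
  res
}

#' Context-dependent test selection for a 2x2 table
#'
#' Chooses between Fisher's exact test and the Pearson chi-square according
#' to the analysis context:
#' \describe{
#'   \item{\code{"simulation"}}{Fisher when \code{N <= 50} or any cell is
#'     below 5; Pearson chi-square otherwise.}
#'   \item{\code{"empirical"}}{Pearson chi-square only for large trials with
#'     \code{N > 5000} and every cell at least 50; Fisher otherwise.}
#' }
#' The chosen test is recorded in \code{test_used}. Significance is always
#' assessed two-sided at \code{p <= alpha}.
#'
#' @inheritParams fisher_exact
#' @param context \code{"empirical"} (default) or \code{"simulation"}.
#' @return A \code{pfrnb_test}.
#' @examples
#' select_test(table2x2(2, 28, 6, 24), context = "simulation")  # Fisher: cell < 5
#' select_test(table2x2(40, 360, 30, 370), context = "simulation")  # chi-square
#' @export
select_test <- function(x, context = c("empirical", "simulation"),
                        alpha = 0.05) {
  context <- match.arg(context)
  x <- as_table2x2(x)
  min_cell <- min(x$a, x$b, x$c, x$d)
  if (.use_fisher(x$n, min_cell, context)) {
    fisher_exact(x, alpha = alpha)
  } else {
    pearson_chisq(x, alpha = alpha)
  }
}

# p-value profile over every event split of one arm, holding the other arm
# fixed. Returns p[e + 1] for e = 0..n_mod events in the modified arm. The
# test-selection rule is re-applied at every split, because a toggle can move
# a cell across the "< 5" Fisher boundary. This is the fragility engine's
# inner loop: Pearson splits are computed in one vectorised pass, Fisher
# splits individually.
.p_profile <- function(n_mod, oe, on, context) {
  e <- 0:n_mod
  ne <- n_mod - e
  N <- n_mod + on
  min_cell <- pmin(e, ne, oe, on - oe)
  fisher <- .use_fisher(N, min_cell, context)
  p <- numeric(n_mod + 1L)
  if (any(!fisher)) {
    idx <- which(!fisher)
    p[idx] <- .pearson_p(e[idx], ne[idx], oe, on - oe)
  }
  if (any(fisher)) {
    idx <- which(fisher)
    p[idx] <- vapply(e[idx], function(ei) {
      .fisher_p(ei, n_mod - ei, oe, on - oe)
    }, numeric(1))
  }
  # Pearson NA can only arise from a zero column margin; treat as p = 1
  p[is.na(p)] <- 1
  p
}
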