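# Fragility: how many single-patient outcome toggles inside one arm flip the
# significance classification across p = 0.05.

# Internal core on plain cells. Returns a plain list; the exported wrapper
# adds the class. `alpha` is fixed at 0.05 in every classification path.
.fragility_core <- function(a, b, c, d, context, alpha = 0.05) {
  n1 <- a + b
  n2 <- c + d
  # modified arm: fewer events; smaller arm on an event tie; arm 1 on a full tie
  if (a < c || (a == c && n1 <= n2)) {
    arm <- 1L; e_obs <- a; n_mod <- n1; oe <- c; on <- n2
  } else {
    arm <- 2L; e_obs <- c; n_mod <- n2; oe <- a; on <- n1
  }
  p <- .p_profile(n_mod, oe, on, context)
  sig <- .is_sig(p, alpha)
  sig_obs <- sig[e_obs + 1L]
  flips <- which(sig != sig_obs) - 1L   # event counts with the other class
  if (length(flips) == 0L) {
    fi <- n_mod
    capped <- TRUE
    test_switched <- FALSE
  } else {
    fi <- min(abs(flips - e_obs))
    capped <- FALSE
    # audit flag: did the selection rule change along the shortest toggle path?
    path <- e_obs + sign(flips[which.min(abs(flips - e_obs))] - e_obs) * (0:fi)
    N <- n_mod + on
    mc <- pmin(path, n_mod - path, oe, on - oe)
    test_switched <- length(unique(.use_fisher(N, mc, context))) > 1L
  }
  list(
    fi = fi,
    modified_arm = arm,
    n_mod = n_mod,
    mfq = fi / n_mod,
    fq = fi / (n_mod + on),
    direction = if (sig_obs) "to_nonsignificant" else "to_significant",
    capped = capped,
    p_value = p[e_obs + 1L],
    test_switched = test_switched
  )
}

#' Which arm is toggled when computing the fragility index?
#'
#' The modified arm is the arm with fewer events; ties on the event count go
#' to the smaller arm, and a full tie to arm 1 for determinism.
#'
#' @param x A \code{table2x2}.
#' @return A list with \code{arm} (1 or 2) and \code{n_mod} (its size).
#' @examples
#' modified_arm(table2x2(2, 18, 6, 14))  # arm 1 (fewer events)
#' modified_arm(table2x2(5, 25, 5, 10))  # arm 2 (event tie, smaller arm)
#' @export
modified_arm <- function(x) {
  x <- as_table2x2(x)
  if (x$a < x$c || (x$a == x$c && x$n1 <= x$n2)) {
    list(arm = 1L, n_mod = x$n1)
  } else {
    list(arm = 2L, n_mod = x$n2)
  }
}

#' Fragility index and modified-arm fragility quotient
#'
#' Computes the minimum number of outcome toggles (event to non-event or the
#' reverse, all in the same direction) inside the modified arm needed to move
#' the trial across the p = 0.05 significance boundary, re-applying the
#' context's test-selection rule after every toggle. Arm sizes never change:
#' toggling only reshuffles the event / non-event split within the modified
#' arm.
#'
#' Significant tables are toggled until they lose significance
#' (\code{direction = "to_nonsignificant"}); nonsignificant tables are
#' toggled until they gain it (a reverse fragility index,
#' \code{"to_significant"}), so stability is defined for every trial. When no
#' achievable event split in the modified arm crosses the boundary, the index
#' is capped at the arm size (\code{capped = TRUE}, MFQ = 1, maximally
#' stable).
#'
#' The quotients normalise the index: MFQ = FI / n_mod (size of the modified
#' arm) and FQ = FI / N (total sample size). MFQ lies in [0, 1]: 0 is
#' maximally fragile, 1 maximally stable.
#'
#' @inheritParams select_test
#' @return A \code{pfrnb_fragility}: list with \code{fi},
#'   \code{modified_arm}, \code{n_mod}, \code{mfq}, \code{fq},
#'   \code{direction}, \code{capped}, \code{p_value} (of the input table
#'   under the selected test) and \code{test_switched} (TRUE when the
#'   test-selection rule changed along the shortest toggle path).
#' @examples
#' fragility_index(table2x2(0, 10, 5, 5), context = "simulation")
#' # fi = 1: (0,10,5,5) is significant, (1,9,5,5) is not
#' @export
fragility_index <- function(x, context = c("empirical", "simulation")) {
  context <- match.arg(context)
  x <- as_table2x2(x)
  res <- .fragility_core(x$a, x$b, x$c, x$d, context)
  class(res) <- "pfrnb_fragility"
  res
}

#' @export
print.pfrnb_fragility <- function(x, ...) {
  cat(sprintf(
    "fragility index %d%s in arm %d (n_mod = %d), %s\n  MFQ = %.4f (%s), FQ = %.4f\n",
    x$fi, if (x$capped) " (capped: no crossing achievable)" else "",
    x$modified_arm, x$n_mod, x$direction,
    x$mfq, classify_stability(x$mfq), x$fq))
  invisible(x)
}

#' Classify stability from the modified-arm fragility quotient
#'
#' Fragile means \code{MFQ <= 0.10} (boundary inclusive); stable means
#' \code{MFQ > 0.10}. The 0.10 cut is heuristic but anchored to the 0.05
#' significance level: under 1:1 allocation, changing 10 percent of one arm
#' equals changing 5 percent of the whole sample (MFQ = 0.10 is FQ = 0.05).
#'
#' @param mfq Numeric vector of quotients in [0, 1].
#' @param threshold Fragility cut point, default 0.10.
#' @return Character vector, \code{"fragile"} or \code{"stable"}.
#' @examples
#' classify_stability(c(0.052, 0.10, 0.102))
#' @export
classify_stability <- function(mfq, threshold = 0.10) {
  if (any(is.na(mfq)) || any(mfq < 0 | mfq > 1)) {
    stop("mfq must lie in [0, 1]", call. = FALSE)
  }
  ifelse(mfq <= threshold, "fragile", "stable")
}
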