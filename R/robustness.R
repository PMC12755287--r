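# Robustness: geometric distance of a 2x2 table from the neutrality boundary
# (ad = bc, identical event odds in both arms) on a 0-1 scale.

#' Risk quotient of a 2x2 table
#'
#' \code{RQ = |ad - bc| / (N^2 / 4)}. The numerator is the (absolute)
#' determinant of the table, zero exactly when the two arms have identical
#' event odds; the denominator is the largest value the numerator can attain
#' for any table of total size N, so RQ always lies in [0, 1]. Higher values
#' indicate stronger separation from therapeutic neutrality.
#'
#' Cell products are formed in double precision (cell counts beyond ~50,000
#' overflow integer multiplication), and the ratio is computed in one final
#' division.
#'
#' @param x A \code{table2x2}.
#' @return The risk quotient, a number in [0, 1].
#' @examples
#' risk_quotient(table2x2(10, 0, 0, 10))  # 1: maximal separation
#' risk_quotient(table2x2(5, 5, 5, 5))    # 0: on the neutrality boundary
#' risk_quotient(table2x2(6, 4, 2, 8))    # 0.40
#' @export
risk_quotient <- function(x) {
  x <- as_table2x2(x)
  .rq(x$a, x$b, x$c, x$d)
}

# vectorised kernel
.rq <- function(a, b, c, d) {
  N <- as.numeric(a) + b + c + d
  abs(as.numeric(a) * d - as.numeric(b) * c) / (N^2 / 4)
}

#' Robustness category thresholds
#'
#' The default cut points 0.075 and 0.227 are the 33rd and 67th percentiles
#' of the risk-quotient distribution from a large prior simulation over
#' realistic trial parameters (sample sizes 30-1,200, event rates 0.03-0.60,
#' relative risks 0.20-3.0); they are consumed here as fixed constants that
#' demarcate weak, moderate and strong robustness.
#'
#' @param weak Upper bound (exclusive) of the weak category. Default 0.075.
#' @param strong Lower bound (inclusive) of the strong category. Default 0.227.
#' @return A named list with \code{weak} and \code{strong}, validated so that
#'   \code{0 < weak < strong < 1}.
#' @export
rq_thresholds <- function(weak = 0.075, strong = 0.227) {
  if (!(is.numeric(weak) && is.numeric(strong) &&
        weak > 0 && weak < strong && strong < 1)) {
    stop("thresholds must satisfy 0 < weak < strong < 1", call. = FALSE)
  }
  list(weak = weak, strong = strong)
}

#' Classify robustness from the risk quotient
#'
#' Weak robustness is \code{RQ < 0.075} (strictly below), strong robustness
#' is \code{RQ >= 0.227} (boundary inclusive), and the half-open band in
#' between is moderate.
#'
#' @param rq Numeric vector of risk quotients in [0, 1].
#' @param thresholds A list from [rq_thresholds()].
#' @return Character vector: \code{"weak"}, \code{"moderate"} or
#'   \code{"strong"}.
#' @examples
#' classify_robustness(c(0.05, 0.075, 0.227))  # weak, moderate, strong
#' @export
classify_robustness <- function(rq, thresholds = rq_thresholds()) {
  if (any(is.na(rq)) || any(rq < 0 | rq > 1)) {
    stop("rq must lie in [0, 1]", call. = FALSE)
  }
  ifelse(rq < thresholds$weak, "weak",
         ifelse(rq >= thresholds$strong, "strong", "moderate"))
}
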