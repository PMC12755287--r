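#' Construct and validate a 2x2 contingency table for a two-arm trial
#'
#' The universal input of the package: one two-arm, binary-outcome trial
#' summarised by four cell counts. Rows are arms, columns are event /
#' non-event. Arm 1 occupies the first row, so \code{a} and \code{b} are the
#' event and non-event counts of arm 1, \code{c} and \code{d} those of arm 2.
#'
#' Validation is strict: all four cells must be non-negative integers, the
#' total \code{N = a + b + c + d} must be at least 1, and both arms must be
#' non-empty (an empty arm leaves the fragility index and the relative risk
#' undefined, so such tables are rejected up front rather than propagated).
#'
#' @param a,b,c,d Cell counts: events / non-events in arm 1, then arm 2.
#'   Numeric values are accepted only when they are whole numbers.
#' @return An object of class \code{"table2x2"}: a list with integer
#'   components \code{a}, \code{b}, \code{c}, \code{d} and derived sizes
#'   \code{n1}, \code{n2}, \code{n}.
#' @examples
#' table2x2(5, 5, 5, 5)
#' table2x2(0, 10, 5, 5)   # a zero cell is legal
#' @seealso [observed_rr()], [analyze_trial()]
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || anyNA(cells)) {
    stop("a 2x2 table needs four non-missing cell counts", call. = FALSE)
  }
  if (!is.numeric(cells)) {
    stop("cell counts must be numeric", call. = FALSE)
  }
  if (any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be whole numbers, got (",
         paste(cells, collapse = ", "), ")", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  if (any(cells < 0L)) {
    stop("cell counts must be non-negative, got (",
         paste(cells, collapse = ", "), ")", call. = FALSE)
  }
  if (sum(cells) < 1L) {
    stop("empty table: total sample size must be at least 1", call. = FALSE)
  }
  n1 <- cells[1L] + cells[2L]
  n2 <- cells[3L] + cells[4L]
  if (n1 == 0L || n2 == 0L) {
    stop("both arms must be non-empty (n1 = ", n1, ", n2 = ", n2, ")",
         call. = FALSE)
  }
  structure(
    list(a = cells[[1L]], b = cells[[2L]], c = cells[[3L]], d = cells[[4L]],
         n1 = n1, n2 = n2, n = n1 + n2),
    class = "table2x2"
  )
}

#' Validate raw cell counts as a 2x2 table
#'
#' Thin wrapper around [table2x2()] that also accepts an existing
#' \code{table2x2} (idempotent) or a length-4 vector in \code{(a, b, c, d)}
#' order.
#'
#' @param x A \code{table2x2}, a length-4 numeric vector, or a 2x2 matrix
#'   with arms as rows and the event column first.
#' @return A validated \code{table2x2}.
#' @export
as_table2x2 <- function(x) {
  if (inherits(x, "table2x2")) {
    return(table2x2(x$a, x$b, x$c, x$d))
  }
  if (is.matrix(x) && all(dim(x) == c(2L, 2L))) {
    return(table2x2(x[1L, 1L], x[1L, 2L], x[2L, 1L], x[2L, 2L]))
  }
  if (is.numeric(x) && length(x) == 4L) {
    return(table2x2(x[[1L]], x[[2L]], x[[3L]], x[[4L]]))
  }
  stop("cannot interpret input as a 2x2 table", call. = FALSE)
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2L, byrow = TRUE,
              dimnames = list(c("arm 1", "arm 2"), c("event", "no event")))
  cat("2x2 trial table (N = ", x$n, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' @export
as.matrix.table2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2L, byrow = TRUE,
         dimnames = list(c("arm1", "arm2"), c("event", "nonevent")))
}

#' Per-arm summary of a 2x2 table
#'
#' @param x A \code{table2x2}.
#' @return A data frame with one row per arm: \code{arm}, \code{n},
#'   \code{events}, \code{event_rate}.
#' @export
arm_summary <- function(x) {
  x <- as_table2x2(x)
  data.frame(
    arm = c(1L, 2L),
    n = c(x$n1, x$n2),
    events = c(x$a, x$c),
    event_rate = c(x$a / x$n1, x$c / x$n2)
  )
}

#' Observed relative risk of a 2x2 table
#'
#' The ratio of the arm-1 event rate to the arm-2 event rate,
#' \code{(a/n1) / (c/n2)}. Purely descriptive; the simulator treats the true
#' relative risk as a data-generating input instead.
#'
#' @param x A \code{table2x2}.
#' @return The relative risk, or \code{NA_real_} when the arm-2 event rate is
#'   zero (the ratio is undefined).
#' @examples
#' observed_rr(table2x2(4, 16, 4, 16))   # 1
#' observed_rr(table2x2(2, 18, 4, 16))   # 0.5
#' @export
observed_rr <- function(x) {
  x <- as_table2x2(x)
  if (x$c == 0L) {
    return(NA_real_)
  }
  (x$a / x$n1) / (x$c / x$n2)
}

# Swap the two arms; used by symmetry property tests and internal checks.
swap_arms <- function(x) {
  x <- as_table2x2(x)
  table2x2(x$c, x$d, x$a, x$b)
}
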