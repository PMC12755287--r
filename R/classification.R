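# Evidence-pattern classification: combine significance, stability and
# robustness into one of five mutually exclusive patterns.

.pattern_levels <- c("CP", "SFW", "concordant_null",
                     "other_significant", "other_nonsignificant")

#' Assign the evidence pattern from a (p, MFQ, RQ) triplet
#'
#' The three named patterns are:
#' \describe{
#'   \item{CP (concordant-positive)}{p <= 0.05, MFQ > 0.10 and RQ >= 0.227:
#'     significant, stable and strongly robust.}
#'   \item{SFW (significant-fragile-weak)}{p <= 0.05, MFQ <= 0.10 and
#'     RQ < 0.075: significant but both fragile and close to neutrality.}
#'   \item{concordant_null}{p > 0.05, MFQ > 0.10 and RQ < 0.075: stably
#'     nonsignificant and close to neutrality.}
#' }
#' Significant trials fitting neither CP nor SFW are
#' \code{other_significant}; nonsignificant trials that are not
#' concordant-null are \code{other_nonsignificant}. Every trial receives
#' exactly one pattern.
#'
#' @param p Two-sided p-value(s) in [0, 1].
#' @param mfq Modified-arm fragility quotient(s) in [0, 1].
#' @param rq Risk quotient(s) in [0, 1].
#' @param thresholds Robustness cut points from [rq_thresholds()].
#' @return A factor with levels \code{CP}, \code{SFW},
#'   \code{concordant_null}, \code{other_significant},
#'   \code{other_nonsignificant}.
#' @examples
#' classify_triplet(0.04, 0.35, 0.55)   # CP
#' classify_triplet(0.04, 0.02, 0.05)   # SFW
#' classify_triplet(0.20, 0.15, 0.03)   # concordant_null
#' @export
classify_triplet <- function(p, mfq, rq, thresholds = rq_thresholds()) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  stability <- classify_stability(mfq)     # validates mfq
  robustness <- classify_robustness(rq, thresholds)  # validates rq
  sig <- .is_sig(p)
  out <- ifelse(sig,
                ifelse(stability == "stable" & robustness == "strong", "CP",
                       ifelse(stability == "fragile" & robustness == "weak",
                              "SFW", "other_significant")),
                ifelse(stability == "stable" & robustness == "weak",
                       "concordant_null", "other_nonsignificant"))
  factor(out, levels = .pattern_levels)
}

#' Full p-fr-nb analysis of one trial table
#'
#' Runs the whole triplet pipeline on a single 2x2 table: context-dependent
#' test selection for the p-value, the modified-arm fragility index and MFQ,
#' the risk quotient, and the evidence-pattern classification.
#'
#' @inheritParams select_test
#' @param thresholds Robustness cut points from [rq_thresholds()].
#' @return A \code{pfrnb_triplet}: list with components \code{table},
#'   \code{test} (a \code{pfrnb_test}), \code{fragility}
#'   (a \code{pfrnb_fragility}), \code{rq}, \code{stability},
#'   \code{robustness} and \code{pattern}.
#' @examples
#' analyze_trial(table2x2(0, 10, 5, 5), context = "simulation")
#' @export
analyze_trial <- function(x, context = c("empirical", "simulation"),
                          thresholds = rq_thresholds()) {
  context <- match.arg(context)
  x <- as_table2x2(x)
  frag <- fragility_index(x, context = context)
  test <- select_test(x, context = context)
  rq <- risk_quotient(x)
  res <- list(
    table = x,
    test = test,
    fragility = frag,
    rq = rq,
    stability = classify_stability(frag$mfq),
    robustness = classify_robustness(rq, thresholds),
    pattern = classify_triplet(test$p_value, frag$mfq, rq, thresholds)
  )
  class(res) <- "pfrnb_triplet"
  res
}

#' @export
print.pfrnb_triplet <- function(x, ...) {
  cat(sprintf(
    "p-fr-nb triplet (N = %d)\n  p  = %.5g (%s, %s)\n  fr = MFQ %.4f (%s; FI %d in arm %d of %d)\n  nb = RQ %.4f (%s)\n  pattern: %s\n",
    x$table$n, x$test$p_value, x$test$test_used,
    if (x$test$significant) "significant" else "not significant",
    x$fragility$mfq, x$stability, x$fragility$fi,
    x$fragility$modified_arm, x$fragility$n_mod,
    x$rq, x$robustness, as.character(x$pattern)))
  invisible(x)
}

# Vectorised engine shared by analyze_trials() and run_grid(): one row per
# table, plain-numeric internals, no per-row S3 dispatch.
.analyze_cells <- function(a, b, c, d, context, thresholds = rq_thresholds()) {
  n <- length(a)
  p <- numeric(n); fi <- integer(n); arm <- integer(n); n_mod <- integer(n)
  capped <- logical(n); direction <- character(n); switched <- logical(n)
  for (i in seq_len(n)) {
    fr <- .fragility_core(a[i], b[i], c[i], d[i], context)
    p[i] <- fr$p_value
    fi[i] <- fr$fi
    arm[i] <- fr$modified_arm
    n_mod[i] <- fr$n_mod
    capped[i] <- fr$capped
    direction[i] <- fr$direction
    switched[i] <- fr$test_switched
  }
  N <- a + b + c + d
  min_cell <- pmin(a, b, c, d)
  test_used <- ifelse(.use_fisher(N, min_cell, context),
                      "fisher_exact", "pearson_chisq")
  mfq <- fi / n_mod
  rq <- .rq(a, b, c, d)
  data.frame(
    a = a, b = b, c = c, d = d, n = N,
    p = p, test_used = test_used, significant = .is_sig(p),
    fi = fi, modified_arm = arm, n_mod = n_mod,
    mfq = mfq, fq = fi / N, capped = capped,
    direction = direction, test_switched = switched,
    rq = rq,
    stability = classify_stability(mfq),
    robustness = classify_robustness(rq, thresholds),
    pattern = classify_triplet(p, mfq, rq, thresholds)
  )
}
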