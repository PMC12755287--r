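# Monte Carlo trial simulator: factorial grids of two-arm binary trials with
# known control event rate and true relative risk, analysed with the
# simulation-context triplet pipeline.

#' Build a factorial scenario grid
#'
#' Crosses the supplied factor levels into one scenario per combination and
#' resolves the allocation split. Scenarios where the intervention event
#' probability \code{cer * rr} would exceed 1 are rejected.
#'
#' @param n_total Integer vector of total sample sizes.
#' @param allocation Character vector of allocation ratios
#'   \code{"r1:r2"} read as intervention:control (e.g. \code{"2:1"} gives
#'   the intervention arm the larger share).
#' @param cer Numeric vector of control event rates in (0, 1).
#' @param rr Numeric vector of true relative risks (> 0); the intervention
#'   event rate is \code{cer * rr}.
#' @return A data frame with one row per scenario: \code{scenario} (index),
#'   \code{n_total}, \code{allocation}, \code{n1}, \code{n2}, \code{cer},
#'   \code{rr}.
#' @examples
#' nrow(scenario_grid(c(60, 100), "1:1", 0.2, c(1, 0.6)))  # 4 scenarios
#' @export
scenario_grid <- function(n_total, allocation, cer, rr) {
  if (any(cer <= 0 | cer >= 1)) stop("cer must lie in (0, 1)", call. = FALSE)
  if (any(rr <= 0)) stop("rr must be positive", call. = FALSE)
  g <- expand.grid(n_total = as.integer(n_total), allocation = allocation,
                   cer = cer, rr = rr,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (any(g$cer * g$rr > 1)) {
    stop("cer * rr must not exceed 1 (invalid event probability)",
         call. = FALSE)
  }
  split <- t(vapply(seq_len(nrow(g)), function(i) {
    split_allocation(g$n_total[i], g$allocation[i])
  }, integer(2)))
  data.frame(scenario = seq_len(nrow(g)),
             n_total = g$n_total, allocation = g$allocation,
             n1 = split[, 1L], n2 = split[, 2L],
             cer = g$cer, rr = g$rr)
}

#' The packaged default simulation grid
#'
#' The 360-scenario factorial benchmark design: total sample sizes 60, 100,
#' 200, 400, 800; allocation ratios 1:1, 2:1 and 3:2
#' (intervention:control); control event rates 0.05, 0.10, 0.20, 0.40; true
#' relative risks 1.00 (null), 0.90, 0.80, 0.70, 0.60 and 1.10. At 2,000
#' replications per scenario this design produces 720,000 trials, of which
#' the null subset (RR = 1.00) contributes 120,000.
#'
#' @param rr Optional subset of relative-risk levels to keep (e.g.
#'   \code{rr = 1} for the 60-scenario null sub-grid).
#' @return A scenario data frame as from [scenario_grid()].
#' @export
default_grid <- function(rr = NULL) {
  g <- scenario_grid(
    n_total = c(60L, 100L, 200L, 400L, 800L),
    allocation = c("1:1", "2:1", "3:2"),
    cer = c(0.05, 0.10, 0.20, 0.40),
    rr = c(1.00, 0.90, 0.80, 0.70, 0.60, 1.10)
  )
  if (!is.null(rr)) {
    g <- g[g$rr %in% rr, , drop = FALSE]
    g$scenario <- seq_len(nrow(g))
    rownames(g) <- NULL
  }
  g
}

#' Split a total sample size by an allocation ratio
#'
#' Arm 1 (intervention) receives \code{round(n_total * r1 / (r1 + r2))} with
#' half-up rounding (0.5 rounds away from zero, so 66.67 of 100 under 2:1
#' becomes 67); arm 2 takes the remainder. A split that would empty either
#' arm is an error.
#'
#' @param n_total Total sample size (>= 2).
#' @param allocation Ratio string \code{"r1:r2"} or numeric length-2 vector.
#' @return Integer vector \code{c(n1, n2)}.
#' @examples
#' split_allocation(60, "3:2")   # 36 24
#' split_allocation(100, "2:1")  # 67 33
#' @export
split_allocation <- function(n_total, allocation) {
  if (is.character(allocation)) {
    parts <- as.numeric(strsplit(allocation, ":", fixed = TRUE)[[1L]])
  } else {
    parts <- as.numeric(allocation)
  }
  if (length(parts) != 2L || anyNA(parts) || any(parts <= 0)) {
    stop("allocation must be a positive ratio like \"2:1\"", call. = FALSE)
  }
  if (n_total < 2L) stop("n_total must be at least 2", call. = FALSE)
  n1 <- as.integer(floor(n_total * parts[1L] / sum(parts) + 0.5))
  n2 <- as.integer(n_total) - n1
  if (n1 < 1L || n2 < 1L) {
    stop("allocation ", paste(parts, collapse = ":"),
         " empties an arm at n_total = ", n_total, call. = FALSE)
  }
  c(n1, n2)
}

# Scenario-level sub-seed derivation: one deterministic draw stream from the
# master seed supplies one sub-seed per scenario, so any scenario can be
# re-simulated in isolation.
.scenario_seeds <- function(master_seed, n_scenarios) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_scenarios)
}

#' Simulate the 2x2 tables of one scenario
#'
#' Event counts are binomial: the control arm (arm 2) draws
#' \code{Binomial(n2, cer)} and the intervention arm (arm 1)
#' \code{Binomial(n1, cer * rr)}.
#'
#' @param scenario One row of a scenario grid (data frame or list with
#'   \code{n1}, \code{n2}, \code{cer}, \code{rr}).
#' @param reps Number of trials to draw.
#' @param seed Integer seed for this scenario.
#' @return A data frame of cell counts \code{a, b, c, d} (arm 1 = intervention
#'   events / non-events, arm 2 = control), one row per trial.
#' @export
simulate_scenario <- function(scenario, reps, seed) {
  if (reps < 1L) stop("reps must be at least 1", call. = FALSE)
  p1 <- scenario$cer * scenario$rr
  if (p1 > 1) stop("cer * rr exceeds 1", call. = FALSE)
  set.seed(seed)
  a <- stats::rbinom(reps, scenario$n1, p1)
  c_ <- stats::rbinom(reps, scenario$n2, scenario$cer)
  data.frame(a = a, b = scenario$n1 - a, c = c_, d = scenario$n2 - c_)
}

#' Run a scenario grid and analyse every simulated trial
#'
#' Simulates \code{reps} trials per scenario and pushes each through the
#' simulation-context triplet pipeline (test selection, fragility index,
#' risk quotient, pattern). Fully reproducible: per-scenario sub-seeds are
#' drawn from one stream seeded with \code{seed}, so the same grid and seed
#' give a bit-identical record table.
#'
#' @param grid A scenario data frame from [scenario_grid()] or
#'   [default_grid()].
#' @param reps Replications per scenario.
#' @param seed Master seed (integer).
#' @param thresholds Robustness cut points from [rq_thresholds()].
#' @param progress Print a progress line per scenario block.
#' @return A data frame with one row per simulated trial: the scenario
#'   factors joined with the full triplet record (cells, p, test used,
#'   fragility, RQ, categories, pattern).
#' @examples
#' g <- scenario_grid(60, "1:1", 0.2, 1)
#' r <- run_grid(g, reps = 5, seed = 1)
#' nrow(r)  # 5
#' @export
run_grid <- function(grid, reps, seed, thresholds = rq_thresholds(),
                     progress = FALSE) {
  seeds <- .scenario_seeds(seed, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    cells <- simulate_scenario(sc, reps, seeds[i])
    rec <- .analyze_cells(cells$a, cells$b, cells$c, cells$d,
                          context = "simulation", thresholds = thresholds)
    rec <- cbind(
      sc[rep(1L, reps), c("scenario", "n_total", "allocation", "cer", "rr")],
      rec
    )
    out[[i]] <- rec
    if (progress) {
      message(sprintf("scenario %d/%d (N=%d %s cer=%.2f rr=%.2f): %d trials",
                      i, nrow(grid), sc$n_total, sc$allocation, sc$cer,
                      sc$rr, reps))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-relative-risk summary of a simulated record table
#'
#' For each true relative risk in the records: the proportion of trials
#' reaching p <= 0.05, and among those significant trials the prevalence of
#' the concordant-positive and significant-fragile-weak patterns, of strong
#' robustness (RQ >= 0.227) and of stability (MFQ > 0.10) — each as a
#' count/denominator proportion with a 95 percent Wilson score interval.
#'
#' @param records A record data frame from [run_grid()] (or any data frame
#'   with columns \code{rr}, \code{significant}, \code{pattern},
#'   \code{robustness}, \code{stability}).
#' @return A data frame with one row per RR level. When an RR level has no
#'   significant trials its prevalence columns are \code{NA} and
#'   \code{undefined} is \code{TRUE}.
#' @export
summarize_grid <- function(records) {
  if (nrow(records) == 0L) stop("no records to summarise", call. = FALSE)
  rr_levels <- sort(unique(records$rr))
  rows <- lapply(rr_levels, function(r) {
    sub <- records[records$rr == r, ]
    n <- nrow(sub)
    sig <- sub[sub$significant, ]
    ns <- nrow(sig)
    sig_prev <- prevalence(ns, n)
    if (ns == 0L) {
      return(data.frame(
        rr = r, n_trials = n, n_significant = 0L,
        prop_significant = sig_prev$proportion,
        sig_ci_low = sig_prev$ci_low, sig_ci_high = sig_prev$ci_high,
        cp = NA_real_, cp_ci_low = NA_real_, cp_ci_high = NA_real_,
        sfw = NA_real_, sfw_ci_low = NA_real_, sfw_ci_high = NA_real_,
        strong = NA_real_, strong_ci_low = NA_real_,
        strong_ci_high = NA_real_,
        stable = NA_real_, stable_ci_low = NA_real_,
        stable_ci_high = NA_real_,
        undefined = TRUE
      ))
    }
    cp <- prevalence(sum(sig$pattern == "CP"), ns)
    sfw <- prevalence(sum(sig$pattern == "SFW"), ns)
    strong <- prevalence(sum(sig$robustness == "strong"), ns)
    stable <- prevalence(sum(sig$stability == "stable"), ns)
    data.frame(
      rr = r, n_trials = n, n_significant = ns,
      prop_significant = sig_prev$proportion,
      sig_ci_low = sig_prev$ci_low, sig_ci_high = sig_prev$ci_high,
      cp = cp$proportion, cp_ci_low = cp$ci_low, cp_ci_high = cp$ci_high,
      sfw = sfw$proportion, sfw_ci_low = sfw$ci_low,
      sfw_ci_high = sfw$ci_high,
      strong = strong$proportion, strong_ci_low = strong$ci_low,
      strong_ci_high = strong$ci_high,
      stable = stable$proportion, stable_ci_low = stable$ci_low,
      stable_ci_high = stable$ci_high,
      undefined = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
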