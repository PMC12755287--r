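# Trial-collection input/output, dataset-level analysis and the synthetic
# fixture generator.

#' Read a trial collection from CSV
#'
#' Expects an RFC-4180 CSV with a header containing at least
#' \code{trial_id, a, b, c, d}; extra columns (e.g. a clinical \code{domain}
#' label) are preserved as metadata. Every row is validated as a 2x2 table;
#' by default any invalid row aborts the read with a message naming the file
#' line.
#'
#' @param path Path to the CSV file.
#' @param skip_invalid If TRUE, drop invalid rows (with a warning listing
#'   their line numbers) instead of aborting.
#' @return A data frame of validated rows, one trial per row.
#' @export
read_trials_csv <- function(path, skip_invalid = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "a", "b", "c", "d")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      table2x2(df$a[i], df$b[i], df$c[i], df$d[i])
      TRUE
    }, error = function(e) {
      bad <<- c(bad, sprintf("line %d (%s): %s", i + 1L, df$trial_id[i],
                             conditionMessage(e)))
      FALSE
    })
    keep[i] <- ok
  }
  if (length(bad) > 0L) {
    if (!skip_invalid) {
      stop("invalid trial rows:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropped invalid trial rows:\n  ", paste(bad, collapse = "\n  "),
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a trial collection (or analysed records) to CSV
#'
#' @param x A data frame of trials or analysed records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Analyse every trial in a collection
#'
#' Runs the full triplet pipeline on each row of a trial data frame and
#' appends the result columns (\code{p, test_used, significant, fi,
#' modified_arm, n_mod, mfq, fq, rq, stability, robustness, pattern}, plus
#' degeneracy/audit flags) to the input columns.
#'
#' @param trials A data frame with columns \code{a, b, c, d} (e.g. from
#'   [read_trials_csv()] or [generate_fixture_trials()]).
#' @param context \code{"empirical"} (default for published trials) or
#'   \code{"simulation"}.
#' @param thresholds Robustness cut points from [rq_thresholds()].
#' @return The input data frame with the triplet columns appended.
#' @export
analyze_trials <- function(trials, context = c("empirical", "simulation"),
                           thresholds = rq_thresholds()) {
  context <- match.arg(context)
  if (nrow(trials) == 0L) stop("no trials to analyse", call. = FALSE)
  res <- .analyze_cells(trials$a, trials$b, trials$c, trials$d,
                        context = context, thresholds = thresholds)
  cbind(trials, res[, setdiff(names(res), c("a", "b", "c", "d"))])
}

#' Pattern and component prevalences of an analysed trial collection
#'
#' Splits the collection by significance and reports, with 95 percent Wilson
#' intervals: among significant trials the prevalence of the
#' concordant-positive and significant-fragile-weak patterns, of fragility
#' (MFQ <= 0.10), weak robustness (RQ < 0.075) and strong robustness
#' (RQ >= 0.227); among nonsignificant trials the concordant-null pattern,
#' stability and strong robustness. Medians and interquartile ranges of MFQ
#' and RQ are reported stratified by significance.
#'
#' @param analyzed A data frame from [analyze_trials()] or [run_grid()].
#' @return A list with elements \code{n_trials}, \code{significant} (a
#'   [prevalence()] row), \code{among_significant},
#'   \code{among_nonsignificant} (data frames of prevalence rows keyed by
#'   \code{measure}) and \code{distributions} (median/IQR of MFQ and RQ by
#'   significance).
#' @export
summarize_trials <- function(analyzed) {
  n <- nrow(analyzed)
  sig <- analyzed[analyzed$significant, , drop = FALSE]
  nsig <- analyzed[!analyzed$significant, , drop = FALSE]
  prev_block <- function(sub, measures) {
    if (nrow(sub) == 0L) return(NULL)
    rows <- lapply(names(measures), function(m) {
      cbind(measure = m, prevalence(sum(measures[[m]](sub)), nrow(sub)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  dist_block <- function(sub, label) {
    if (nrow(sub) == 0L) return(NULL)
    data.frame(
      group = label,
      metric = c("mfq", "rq"),
      median = c(stats::median(sub$mfq), stats::median(sub$rq)),
      q1 = c(stats::quantile(sub$mfq, 0.25, names = FALSE),
             stats::quantile(sub$rq, 0.25, names = FALSE)),
      q3 = c(stats::quantile(sub$mfq, 0.75, names = FALSE),
             stats::quantile(sub$rq, 0.75, names = FALSE))
    )
  }
  list(
    n_trials = n,
    significant = prevalence(nrow(sig), n),
    among_significant = prev_block(sig, list(
      cp = function(s) s$pattern == "CP",
      sfw = function(s) s$pattern == "SFW",
      fragile = function(s) s$stability == "fragile",
      stable = function(s) s$stability == "stable",
      weak = function(s) s$robustness == "weak",
      moderate = function(s) s$robustness == "moderate",
      strong = function(s) s$robustness == "strong"
    )),
    among_nonsignificant = prev_block(nsig, list(
      concordant_null = function(s) s$pattern == "concordant_null",
      stable = function(s) s$stability == "stable",
      strong = function(s) s$robustness == "strong"
    )),
    distributions = rbind(dist_block(sig, "significant"),
                          dist_block(nsig, "nonsignificant"))
  )
}

#' Generate a synthetic trial collection
#'
#' Produces a deterministic, heterogeneous collection of synthetic 2x2
#' trials: total sample sizes are drawn log-uniformly between the given
#' bounds, control event rates uniformly, allocation ratios from a small set
#' of realistic values, and each trial's true relative risk from the supplied
#' effect mixture. It stands in for unpublished empirical collections in
#' examples and tests; it makes no claim to reproduce any published
#' dataset's prevalences.
#'
#' The generator asserts that the collection exercises all five evidence
#' patterns (under the empirical analysis context). If a pattern is missing
#' it retries with an incremented sub-seed up to \code{max_retries} times,
#' then errors.
#'
#' @param n_trials Number of trials to generate (>= 1).
#' @param effect_mixture A data frame with columns \code{rr} and
#'   \code{weight} (weights sum to 1): the mixture of true relative risks.
#' @param size_range Length-2 bounds on total sample size (log-uniform).
#' @param cer_range Length-2 bounds on the control event rate (uniform).
#' @param seed Integer seed.
#' @param max_retries Bounded retries when a pattern class is missing.
#' @return A data frame with columns \code{trial_id, a, b, c, d, domain,
#'   true_rr, n_total}.
#' @examples
#' fx <- generate_fixture_trials(100, seed = 42)
#' table(analyze_trials(fx)$pattern) > 0
#' @export
generate_fixture_trials <- function(n_trials,
                                    effect_mixture = data.frame(
                                      rr = c(1.0, 0.8, 0.6, 0.4, 1.5),
                                      weight = c(0.35, 0.15, 0.2, 0.15, 0.15)),
                                    size_range = c(20, 2000),
                                    cer_range = c(0.05, 0.5),
                                    seed = 1,
                                    max_retries = 20L) {
  if (n_trials < 1L) stop("n_trials must be at least 1", call. = FALSE)
  if (abs(sum(effect_mixture$weight) - 1) > 1e-8) {
    stop("effect mixture weights must sum to 1", call. = FALSE)
  }
  if (any(size_range < 4) || size_range[1] > size_range[2]) {
    stop("size_range must be increasing and at least 4", call. = FALSE)
  }
  gen_once <- function(s) {
    set.seed(s)
    n_total <- as.integer(round(exp(stats::runif(
      n_trials, log(size_range[1]), log(size_range[2])))))
    n_total <- pmax(n_total, 4L)
    alloc <- sample(c("1:1", "1:1", "2:1", "3:2"), n_trials, replace = TRUE)
    cer <- stats::runif(n_trials, cer_range[1], cer_range[2])
    rr <- sample(effect_mixture$rr, n_trials, replace = TRUE,
                 prob = effect_mixture$weight)
    p1 <- pmin(cer * rr, 0.99)
    rows <- lapply(seq_len(n_trials), function(i) {
      ns <- split_allocation(n_total[i], alloc[i])
      a <- stats::rbinom(1L, ns[1], p1[i])
      c_ <- stats::rbinom(1L, ns[2], cer[i])
      data.frame(a = a, b = ns[1] - a, c = c_, d = ns[2] - c_)
    })
    cells <- do.call(rbind, rows)
    data.frame(
      trial_id = sprintf("synthetic_%04d", seq_len(n_trials)),
      cells,
      domain = sample(c("cardiology", "endocrinology", "oncology",
                        "infectious_disease", "neurology"),
                      n_trials, replace = TRUE),
      true_rr = rr,
      n_total = n_total
    )
  }
  for (attempt in 0:max_retries) {
    fx <- gen_once(seed + attempt)
    patterns <- analyze_trials(fx, context = "empirical")$pattern
    if (all(.pattern_levels %in% patterns)) {
      attr(fx, "seed_used") <- seed + attempt
      return(fx)
    }
  }
  stop("could not produce all five evidence patterns in ", max_retries,
       " retries; enlarge n_trials or widen the mixture", call. = FALSE)
}

#' Read a scenario-grid configuration file
#'
#' YAML (or JSON) listing the factor levels \code{n_total},
#' \code{allocation}, \code{cer}, \code{rr} and optionally \code{reps}. The
#' packaged default grid configuration ships as
#' \code{system.file("extdata", "grid_default.yaml", package = "pfrnb")}.
#'
#' @param path Path to the configuration file.
#' @return A list with \code{grid} (a scenario data frame) and \code{reps}
#'   (NULL when the file does not set it).
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("n_total", "allocation", "cer", "rr")
  missing_keys <- setdiff(needed, names(cfg))
  if (length(missing_keys) > 0L) {
    stop("grid config missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  list(
    grid = scenario_grid(cfg$n_total, as.character(cfg$allocation),
                         cfg$cer, cfg$rr),
    reps = cfg$reps
  )
}

#' Write a summary object to JSON
#'
#' @param x A summary list or data frame (e.g. from [summarize_trials()] or
#'   [summarize_grid()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
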