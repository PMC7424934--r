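# Behavioural-experiment utilities: the stimulus sets shown to observers,
# synthetic trial tables, and proportion scoring with Wilson confidence
# intervals.

#' Stimulus sets of the two-alternative lightness experiments
#'
#' The single-stimulus set holds the twelve judged figures (the
#' first-experiment argyle variants plus the nine other illusions) and the
#' left-right mirror reversal of each: 24 stimuli. The paired set holds the
#' seven illusion-strength comparisons in both left/right placements: 14
#' ordered pairs.
#'
#' @return A list with `single` (list of 24 `mir_stimulus` objects) and
#'   `pairs` (data.frame with `pair_id`, `left`, `right`, `expected_side`).
#' @export
make_experiment_sets <- function() {
  base12 <- c("argyle_exp1", "long_range_argyle_exp1", "argyle_control_exp1",
              "koffka_broken", "koffka_adelson", "koffka_connected",
              "whites", "checkerboard", "snake", "snake_control",
              "simultaneous_contrast", "articulated_sc")
  single <- list()
  for (nm in base12) {
    single[[length(single) + 1L]] <- mir_stimulus(nm, mirrored = FALSE)
    single[[length(single) + 1L]] <- mir_stimulus(nm, mirrored = TRUE)
  }
  p <- data.frame(
    stronger = c("argyle_exp1", "long_range_argyle_exp1", "argyle_exp1",
                 "snake", "koffka_broken", "koffka_adelson", "articulated_sc"),
    weaker = c("argyle_control_exp1", "argyle_control_exp1",
               "simultaneous_contrast", "snake_control", "koffka_connected",
               "koffka_connected", "simultaneous_contrast"),
    stringsAsFactors = FALSE
  )
  pairs <- rbind(
    data.frame(pair_id = paste0(p$stronger, "_vs_", p$weaker),
               left = p$stronger, right = p$weaker, expected_side = "left",
               stringsAsFactors = FALSE),
    data.frame(pair_id = paste0(p$stronger, "_vs_", p$weaker),
               left = p$weaker, right = p$stronger, expected_side = "right",
               stringsAsFactors = FALSE)
  )
  pairs <- pairs[order(pairs$pair_id, pairs$expected_side), ]
  rownames(pairs) <- NULL
  list(single = single, pairs = pairs)
}

#' Expected response side for a single-stimulus condition
#'
#' The expected-lighter (green) target lies on the left in the unmirrored
#' figures and on the right in their mirror reversals.
#'
#' @param stimulus_id Catalogue name.
#' @param mirrored Mirrored presentation?
#' @return `"left"` or `"right"` (or `NA` for non-scorable figures).
#' @export
expected_side <- function(stimulus_id, mirrored = FALSE) {
  s <- mir_stimulus(stimulus_id, mirrored = mirrored)
  if (!isTRUE(s$scorable) || is.null(s$targets)) return(NA_character_)
  W <- ncol(s$reflectance)
  if (mean(s$targets$green[, 2]) < mean(s$targets$red[, 2])) "left" else "right"
}

#' Generate a synthetic trial table
#'
#' Seeded binomial responses emulating the experiment's format: every
#' observer responds once per condition, choosing the expected side with
#' probability `p` (after an optional share of "same" responses).
#'
#' @param proportions Named numeric vector: condition id -> probability of
#'   choosing the expected side.
#' @param expected Named character vector: condition id -> expected side
#'   (`"left"`/`"right"`); defaults to `"left"` for all conditions.
#' @param n_observers Observers (trials per condition).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param same_rate Probability of a "same" response (counted half toward
#'   each side when scoring).
#' @return A data.frame with columns `observer`, `condition`, `placement`,
#'   `response`.
#' @export
synth_trials <- function(proportions, expected = NULL, n_observers = 20L,
                         seed = 1L, same_rate = 0) {
  if (any(proportions < 0 | proportions > 1)) stop("proportions must be in [0, 1]")
  if (same_rate < 0 || same_rate > 1) stop("same_rate must be in [0, 1]")
  if (is.null(names(proportions))) stop("proportions must be named by condition")
  if (is.null(expected)) {
    expected <- stats::setNames(rep("left", length(proportions)), names(proportions))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- list()
  for (cond in names(proportions)) {
    p <- proportions[[cond]]
    exp_side <- expected[[cond]]
    other <- if (exp_side == "left") "right" else "left"
    for (obs in seq_len(n_observers)) {
      u <- stats::runif(1)
      resp <- if (u < same_rate) "same" else {
        if (stats::runif(1) < p) exp_side else other
      }
      rows[[length(rows) + 1L]] <- data.frame(
        observer = obs, condition = cond, placement = exp_side,
        response = resp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Wilson score confidence interval
#'
#' @param successes Number (possibly fractional) of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - hw), min(1, centre + hw))
}

#' Score expected-choice proportions from a trial table
#'
#' "Same" responses contribute half a trial to each side, so they add 0.5
#' to the expected count. Each condition gets the proportion of
#' expected-side choices with a 95% Wilson confidence interval.
#'
#' @param trials data.frame with columns `condition`, `response`, and
#'   (optionally) `placement`.
#' @param expected_map Named character vector: condition -> expected side.
#'   When missing and the table has a `placement` column, the placement is
#'   used as the expected side.
#' @param conf Confidence level for the interval.
#' @return data.frame with `condition`, `n_trials`, `expected_count`,
#'   `proportion`, `ci_low`, `ci_high`.
#' @export
score_expected_proportion <- function(trials, expected_map = NULL, conf = 0.95) {
  stopifnot(all(c("condition", "response") %in% names(trials)))
  if (!all(trials$response %in% c("left", "right", "same"))) {
    stop("responses must be 'left', 'right' or 'same'")
  }
  conds <- unique(trials$condition)
  if (!is.null(expected_map) && !all(conds %in% names(expected_map))) {
    stop("expected_map is missing some conditions")
  }
  out <- lapply(conds, function(cond) {
    tt <- trials[trials$condition == cond, , drop = FALSE]
    exp_side <- if (!is.null(expected_map)) expected_map[[cond]] else
      tt$placement
    credit <- sum((tt$response == exp_side) + 0.5 * (tt$response == "same"))
    n <- nrow(tt)
    ci <- wilson_ci(credit, n, conf)
    data.frame(condition = cond, n_trials = n, expected_count = credit,
               proportion = credit / n, ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write trial tables
#'
#' Headered CSV with columns `observer`, `condition`, `placement`,
#' `response`; round-trips exactly.
#'
#' @param trials Trial data.frame.
#' @param path CSV path.
#' @return `read_trials` returns the data.frame; `write_trials` the path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer", "condition", "placement", "response")
  if (!all(need %in% names(tt))) {
    stop("trial table must have columns observer, condition, placement, response")
  }
  tt
}
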