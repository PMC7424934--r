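# Illusion scoring, the qualitative prediction matrix, and the four
# phenomena probes (highest-luminance anchoring, glow, codetermination,
# articulation).

#' Score a model output into an illusion prediction
#'
#' Means of the model's output over the two target-cell sets; the verdict
#' is `"expected"` if the green (expected-lighter) mean exceeds the red
#' mean by more than the dead-band, `"reverse"` if the opposite holds, and
#' `"none"` otherwise. For reflectance maps the dead-band is in reflectance
#' units; for comparison-model maps (arbitrary units) it is the same
#' fraction of the map's range.
#'
#' @param x A `mir_fit`, a `mir_response`, or a plain matrix.
#' @param targets Target list with `green`/`red` cell matrices; taken from
#'   the attached stimulus when omitted.
#' @param threshold Dead-band (reflectance units), default 0.01.
#' @return A `mir_illusion` row: list with `stimulus`, `model`,
#'   `green_mean`, `red_mean`, `difference` (green minus red), `verdict`.
#' @export
illusion_difference <- function(x, targets = NULL, threshold = 0.01) {
  if (inherits(x, "mir_fit")) {
    map <- x$reflectance
    stim <- x$stimulus
    model <- "mir"
    theta <- threshold
  } else if (inherits(x, "mir_response")) {
    map <- x$map
    stim <- x$stimulus
    model <- x$model
    theta <- if (x$model == "mir") threshold else threshold * x$scale
  } else {
    map <- x
    stim <- NULL
    model <- "map"
    theta <- threshold
  }
  if (is.null(targets)) {
    if (is.null(stim) || is.null(stim$targets)) {
      stop("no scorable targets available for this input")
    }
    targets <- stim$targets
  }
  if (!nrow(targets$green) || !nrow(targets$red)) stop("empty target sets")
  gm <- mean(map[targets$green])
  rm_ <- mean(map[targets$red])
  d <- gm - rm_
  verdict <- if (d > theta) "expected" else if (d < -theta) "reverse" else "none"
  structure(list(stimulus = if (is.null(stim)) NA_character_ else stim$name,
                 model = model, green_mean = gm, red_mean = rm_,
                 difference = d, verdict = verdict, threshold = theta),
            class = "mir_illusion")
}

#' @export
print.mir_illusion <- function(x, ...) {
  cat(sprintf("%s on %s: green %.4g, red %.4g, difference %+.4g -> %s\n",
              x$model, x$stimulus, x$green_mean, x$red_mean, x$difference,
              x$verdict))
  invisible(x)
}

#' Compare the strength of two illusion results
#'
#' Compares absolute target differences from the same model with the same
#' dead-band logic used for single verdicts.
#'
#' @param a,b `mir_illusion` results for two stimuli.
#' @param threshold Dead-band on the strength difference; defaults to the
#'   larger of the two results' own dead-bands.
#' @return `"a_stronger"`, `"b_stronger"` or `"tie"`.
#' @export
pair_strength <- function(a, b, threshold = NULL) {
  stopifnot(inherits(a, "mir_illusion"), inherits(b, "mir_illusion"))
  if (a$model != b$model) stop("pair comparison requires the same model")
  if (is.null(threshold)) threshold <- max(a$threshold, b$threshold)
  d <- abs(a$difference) - abs(b$difference)
  if (d > threshold) "a_stronger" else if (d < -threshold) "b_stronger" else "tie"
}

table1_singles <- function() {
  data.frame(
    row = c("argyle", "broken_argyle", "snake", "snake_control",
            "koffka_broken", "koffka_adelson", "koffka_connected",
            "simultaneous_contrast", "articulated_sc", "whites",
            "checkerboard"),
    stimulus = c("argyle", "long_range_argyle", "snake", "snake_control",
                 "koffka_broken", "koffka_adelson", "koffka_connected",
                 "simultaneous_contrast", "articulated_sc", "whites",
                 "checkerboard"),
    human = c("expected", "expected", "expected", "expected", "expected",
              "expected", "none", "expected", "expected", "expected",
              "expected"),
    stringsAsFactors = FALSE
  )
}

table1_pairs <- function() {
  data.frame(
    row = c("argyle_vs_control", "snake_vs_control",
            "koffka_broken_vs_connected", "koffka_adelson_vs_connected",
            "articulated_vs_sc", "argyle_vs_sc", "snake_vs_sc"),
    stronger = c("argyle", "snake", "koffka_broken", "koffka_adelson",
                 "articulated_sc", "argyle", "snake"),
    weaker = c("argyle_control", "snake_control", "koffka_connected",
               "koffka_connected", "simultaneous_contrast",
               "simultaneous_contrast", "simultaneous_contrast"),
    stringsAsFactors = FALSE
  )
}

#' Qualitative prediction matrix over the illusion battery
#'
#' Evaluates each requested model on the eleven single-stimulus rows and
#' seven illusion-vs-control strength comparisons of the battery, and marks
#' every entry as a correct or incorrect qualitative prediction of the
#' perceptual result. A single-stimulus row counts as correct when the
#' model reproduces the illusion human observers see (for the
#' connected-Koffka control, where observers see no reliable illusion,
#' any verdict except a reverse effect counts); a pair row counts as
#' correct when the model ranks the two illusion strengths the way
#' observers do.
#'
#' @param models Character vector of models to evaluate.
#' @param params [mir_params()] used by the decomposition model.
#' @param verbose Print progress.
#' @return A data.frame with one row per battery entry and, per model,
#'   columns `<model>` (logical: correct) and `<model>_diff`.
#' @export
table1_matrix <- function(models = c("mir", "odog", "highpass", "retinex"),
                          params = mir_params(), verbose = FALSE) {
  singles <- table1_singles()
  pairs <- table1_pairs()
  stim_names <- unique(c(singles$stimulus, pairs$stronger, pairs$weaker))
  out <- data.frame(row = c(singles$row, pairs$row),
                    type = c(rep("single", nrow(singles)),
                             rep("pair", nrow(pairs))),
                    stringsAsFactors = FALSE)
  for (model in models) {
    scores <- list()
    for (nm in stim_names) {
      if (verbose) message(sprintf("[table1] %s on %s", model, nm))
      scores[[nm]] <- illusion_difference(run_model(model, nm, params = params))
    }
    ok <- logical(nrow(out)); dif <- numeric(nrow(out))
    for (r in seq_len(nrow(singles))) {
      sc <- scores[[singles$stimulus[r]]]
      dif[r] <- sc$difference
      ok[r] <- if (singles$human[r] == "expected") {
        sc$verdict == "expected"
      } else {
        sc$verdict != "reverse"
      }
    }
    for (r in seq_len(nrow(pairs))) {
      cmp <- pair_strength(scores[[pairs$stronger[r]]], scores[[pairs$weaker[r]]])
      i <- nrow(singles) + r
      ok[i] <- cmp == "a_stronger"
      dif[i] <- abs(scores[[pairs$stronger[r]]]$difference) -
        abs(scores[[pairs$weaker[r]]]$difference)
    }
    out[[model]] <- ok
    out[[paste0(model, "_diff")]] <- dif
  }
  out
}

#' Highest-luminance statistics per inferred lighting region
#'
#' Segments the fitted illuminance map into uniform regions and reports the
#' maximum reflectance inside each, together with the smallest illuminance
#' step on the region's boundary. Regions whose boundary steps all exceed
#' `seg_threshold` (log10 units) count as strongly segmented lighting
#' frameworks; within those, the anchoring behaviour predicts a maximum
#' reflectance near white.
#'
#' @param fit A `mir_fit`.
#' @param seg_threshold Strong-segmentation threshold; defaults to the
#'   fitted parameters' value.
#' @return data.frame with `region`, `size`, `max_reflectance`,
#'   `min_boundary_step`, `strong`.
#' @export
highest_luminance_stats <- function(fit, seg_threshold = fit$params$seg_threshold) {
  stopifnot(inherits(fit, "mir_fit"))
  lab <- segment_regions(fit$illuminance, tol = 1e-9)$labels
  st <- fit$states
  H <- nrow(lab); W <- ncol(lab)
  n_reg <- max(lab)
  minstep <- rep(Inf, n_reg)
  step_lev <- fit$levels
  note_edge <- function(l1, l2, s1, s2) {
    if (l1 != l2) {
      d <- abs(step_lev[s1] - step_lev[s2])
      if (d < minstep[l1]) minstep[l1] <<- d
      if (d < minstep[l2]) minstep[l2] <<- d
    }
  }
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (c < W) note_edge(lab[r, c], lab[r, c + 1], st[r, c], st[r, c + 1])
    if (r < H) note_edge(lab[r, c], lab[r + 1, c], st[r, c], st[r + 1, c])
  }
  data.frame(
    region = seq_len(n_reg),
    size = tabulate(lab, n_reg),
    max_reflectance = vapply(seq_len(n_reg), function(l)
      max(fit$reflectance[lab == l]), numeric(1)),
    min_boundary_step = minstep,
    strong = minstep > seg_threshold
  )
}

#' Phenomena probe curves
#'
#' `glow_curve`: reflectance (or model response) assigned to a centred
#' luminance outlier as its width grows; `codetermination_curve`: output at
#' the left centre patch of the simultaneous-contrast figure as the
#' luminance of the *right* surround varies; `articulation_curve`: median
#' simultaneous-contrast effect (green minus red target mean) as the
#' surrounds are subdivided into more jittered blocks.
#'
#' @param widths Outlier widths in cells.
#' @param model `"mir"`, `"odog"`, `"highpass"` or `"retinex"`.
#' @param params [mir_params()] for the decomposition model.
#' @param ... Passed to [run_model()].
#' @return A data.frame, one row per probe point.
#' @export
glow_curve <- function(widths = c(1, 2, 4, 6, 8), model = "mir",
                       params = mir_params(), ...) {
  vals <- vapply(widths, function(w) {
    s <- glow_stimulus(w)
    res <- run_model(model, s, params = params, ...)
    outlier <- mean(res$map[s$probe_cells])
    if (model == "mir") outlier else {
      bg <- res$map
      bg[s$probe_cells] <- NA
      outlier - mean(bg, na.rm = TRUE)
    }
  }, numeric(1))
  data.frame(width = widths, value = vals, model = model)
}

#' @rdname glow_curve
#' @param luminances Right-surround luminances in cd/m^2.
#' @export
codetermination_curve <- function(luminances = c(60, 89, 130, 200),
                                  model = "mir", params = mir_params(), ...) {
  vals <- vapply(luminances, function(L) {
    s <- codetermination_stimulus(L)
    res <- run_model(model, s, params = params, ...)
    mean(res$map[s$targets$green])
  }, numeric(1))
  data.frame(right_surround = luminances, value = vals, model = model)
}

#' @rdname glow_curve
#' @param n_subblocks_list Subblock counts per surround half.
#' @param n_samples Stimulus samples per count (the printed figure uses
#'   100; tests use fewer).
#' @param seed Base seed for the jittered stimuli.
#' @param jitter_sd Log-normal jitter of block luminances.
#' @export
articulation_curve <- function(n_subblocks_list = c(1, 4, 16, 64),
                               n_samples = 100L, seed = 1L, jitter_sd = 0.3,
                               model = "mir", params = mir_params(), ...) {
  med <- vapply(seq_along(n_subblocks_list), function(ni) {
    effects <- vapply(seq_len(n_samples), function(s) {
      sd_seed <- (seed + 7919L * s + 104729L * ni) %% 2147483647L
      stim <- articulated_variant(n_subblocks_list[ni], jitter_sd, sd_seed)
      res <- run_model(model, stim, params = params, ...)
      mean(res$map[stim$targets$green]) - mean(res$map[stim$targets$red])
    }, numeric(1))
    stats::median(effects)
  }, numeric(1))
  data.frame(n_subblocks = n_subblocks_list, effect = med, model = model)
}
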