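# MAP inference: max-sum belief propagation on the patch cluster graph,
# an exhaustive oracle for small instances, and the user-facing fitting
# function mir_decompose() with its S3 methods.

fit_from_states <- function(crf, states, iterations, converged, method,
                            stimulus = NULL) {
  ill <- matrix(10^crf$levels[states], crf$H, crf$W)
  refl <- crf$grid / ill
  structure(
    list(illuminance = ill, reflectance = refl,
         states = matrix(as.integer(states), crf$H, crf$W),
         energy = crf_energy(crf, matrix(as.integer(states), crf$H, crf$W)),
         converged = converged, iterations = iterations, method = method,
         luminance = crf$grid, levels = crf$levels, params = crf$params,
         stimulus = stimulus),
    class = "mir_fit"
  )
}

#' Max-sum belief propagation on a patch CRF
#'
#' Synchronous message passing between overlapping 2x2 patch clusters; each
#' message lives on the 1x2 cell pair two neighbouring patches share.
#' Messages are max-normalised each round and damped; decoding takes the
#' per-variable argmin of the summed cluster min-marginals, with ties going
#' to the lowest (darkest) level. On loopy graphs convergence is not
#' guaranteed; non-convergence is reported in the result, not an error.
#'
#' @param crf A [mir_crf()] object.
#' @param damping Message damping in `[0, 1)`; default from the CRF params.
#' @param max_iter Maximum rounds.
#' @param tol Stop when no message component changes by more than this.
#' @param polish Refine the decoded state by single-cell coordinate descent
#'   until no single-cell change lowers the energy.
#' @return A `mir_fit` object (see [mir_decompose()]).
#' @export
max_sum_bp <- function(crf, damping = crf$params$damping,
                       max_iter = crf$params$max_iter,
                       tol = crf$params$bp_tol,
                       polish = crf$params$polish) {
  stopifnot(inherits(crf, "mir_crf"), damping >= 0, damping < 1, max_iter >= 1)
  res <- mir_bp_cpp(crf$tables, crf$unary, crf$H, crf$W,
                    length(crf$levels), crf$w_corner, damping,
                    as.integer(max_iter), tol)
  states <- res$states + 1L
  if (polish) {
    states <- polish_states(crf, states)
  }
  fit_from_states(crf, states, res$iterations, res$converged, "max_sum_bp")
}

# Deterministic refinement of a decoded assignment: region-coordinated
# coordinate descent (whole uniform luminance regions move together, which
# discovers lighting splits that single-cell moves cannot) followed by
# single-cell descent, applied to the decoded state and to every flat
# (uniform-level) start; the lowest-energy result wins.
polish_states <- function(crf, states) {
  n <- length(crf$levels)
  labels0 <- as.integer(crf$regions$labels) - 1L
  refine <- function(st0) {
    r1 <- mir_region_icm_cpp(crf$tables, crf$unary, as.integer(st0) - 1L,
                             labels0, crf$H, crf$W, n, crf$w_corner, 100L)
    r2 <- mir_shift_icm_cpp(crf$tables, crf$unary, r1$states, labels0,
                            crf$H, crf$W, n, crf$w_corner, 12L, 50L)
    r3 <- mir_icm_cpp(crf$tables, crf$unary, r2$states, crf$H, crf$W, n,
                      crf$w_corner, 200L)
    r4 <- mir_region_icm_cpp(crf$tables, crf$unary, r3$states, labels0,
                             crf$H, crf$W, n, crf$w_corner, 100L)
    r4$states + 1L
  }
  best <- refine(states)
  best_e <- crf_energy(crf, matrix(best, crf$H, crf$W))
  flat_e <- vapply(seq_len(n), function(lev)
    crf_energy(crf, matrix(lev, crf$H, crf$W)), numeric(1))
  for (lev in order(flat_e)[seq_len(min(3L, n))]) {
    cand <- refine(rep(lev, crf$H * crf$W))
    e <- crf_energy(crf, matrix(cand, crf$H, crf$W))
    if (e < best_e - 1e-12) { best <- cand; best_e <- e }
  }
  # a final single-cell pass so the returned state is a local optimum
  fin <- mir_icm_cpp(crf$tables, crf$unary, as.integer(best) - 1L,
                     crf$H, crf$W, n, crf$w_corner, 200L)
  fin$states + 1L
}

#' Exhaustive MAP oracle
#'
#' Finds the global minimum-energy assignment by enumerating every state
#' combination. Only feasible for tiny instances (state count at most 1e7);
#' used as the ground-truth oracle for the belief-propagation solver.
#'
#' @param crf A [mir_crf()] object.
#' @return A `mir_fit` object with `method = "exhaustive"`.
#' @export
exhaustive_map <- function(crf) {
  stopifnot(inherits(crf, "mir_crf"))
  res <- mir_exhaustive_cpp(crf$tables, crf$unary, crf$H, crf$W,
                            length(crf$levels), crf$w_corner)
  fit_from_states(crf, res$states + 1L, 0L, TRUE, "exhaustive")
}

#' Decompose a luminance image into illuminance and reflectance
#'
#' The headline entry point: builds the conditional random field for the
#' stimulus and finds the maximum a posteriori split of the observed
#' luminance into an illuminance map and a reflectance map whose pointwise
#' product reproduces the input exactly. The reflectance map is the model's
#' lightness prediction.
#'
#' @param stimulus A `mir_stimulus`, or a positive luminance matrix
#'   (cd/m^2).
#' @param params A [mir_params()] object.
#' @param ... Passed to [max_sum_bp()] (e.g. `max_iter`, `damping`).
#' @return A `mir_fit` object: list with `illuminance`, `reflectance`,
#'   `energy`, `converged`, `iterations`, the input `luminance`, the level
#'   grid, and the stimulus (if one was given). Methods: `print`,
#'   `summary`, `plot`, `fitted` (reconstructed luminance), `residuals`
#'   (log10 reconstruction error, identically zero by construction).
#' @examples
#' \donttest{
#' fit <- mir_decompose(mir_stimulus("simultaneous_contrast"))
#' illusion_difference(fit)
#' }
#' @export
mir_decompose <- function(stimulus, params = mir_params(), ...) {
  stim <- if (inherits(stimulus, "mir_stimulus")) stimulus else NULL
  crf <- mir_crf(stimulus, params)
  fit <- max_sum_bp(crf, ...)
  fit$stimulus <- stim
  fit
}

#' @export
print.mir_fit <- function(x, ...) {
  cat(sprintf("Illuminance/reflectance decomposition (%s)\n", x$method))
  if (!is.null(x$stimulus)) cat(sprintf("  stimulus   : %s%s\n", x$stimulus$name,
                                        if (x$stimulus$mirrored) " (mirrored)" else ""))
  cat(sprintf("  grid       : %d x %d, %d levels\n", nrow(x$luminance),
              ncol(x$luminance), length(x$levels)))
  cat(sprintf("  energy     : %.6f\n", x$energy))
  cat(sprintf("  iterations : %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  reflectance: %.3f - %.3f; illuminance: %.1f - %.1f\n",
              min(x$reflectance), max(x$reflectance),
              min(x$illuminance), max(x$illuminance)))
  invisible(x)
}

#' @export
summary.mir_fit <- function(object, ...) {
  print(object)
  segs <- highest_luminance_stats(object)
  cat(sprintf("  lighting frameworks: %d (%d strongly segmented)\n",
              nrow(segs), sum(segs$strong)))
  if (!is.null(object$stimulus) && isTRUE(object$stimulus$scorable)) {
    ir <- illusion_difference(object)
    cat(sprintf("  targets: green %.3f, red %.3f, difference %+.4f -> %s\n",
                ir$green_mean, ir$red_mean, ir$difference, ir$verdict))
  }
  invisible(object)
}

#' @export
fitted.mir_fit <- function(object, ...) {
  object$illuminance * object$reflectance
}

#' @export
residuals.mir_fit <- function(object, ...) {
  log10(fitted(object)) - log10(object$luminance)
}

#' @export
plot.mir_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main, zlim = range(m)) {
    if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, main = main,
                    col = grDevices::gray.colors(128, 0, 1), zlim = zlim, ...)
  }
  show(x$luminance, "luminance (cd/m2)")
  show(log10(x$illuminance), "log illuminance")
  show(x$reflectance, "reflectance", zlim = c(0, max(1, max(x$reflectance))))
  invisible(x)
}
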