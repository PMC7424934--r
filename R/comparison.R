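# Comparison models: oriented difference-of-Gaussians (ODOG), linear
# high-pass filtering, and multiscale ratio-propagation retinex. All three
# operate on upsampled pixel images (the 16-cell stimulus spans 512 px = 8
# deg of visual angle, centred in a mean-luminance canvas) and are read out
# after block-averaging back to the stimulus grid.

#' Oriented difference-of-Gaussians brightness model
#'
#' Six orientations x seven spatial scales of oriented DoG filters (2:1
#' surround elongation along the filter axis), across-scale weighted sums
#' per orientation (weights increasing with spatial frequency, exponent
#' 0.1), RMS response normalisation within each orientation, and a final
#' sum across orientations. Filtering is done in the frequency domain.
#'
#' @param image A [mir_upsample()] canvas (luminance).
#' @param n_orient,n_scales Filter bank size.
#' @param sigma_px Centre Gaussian space constants in pixels, finest to
#'   coarsest; defaults to octave spacing 3 to 192 px (0.047 to 3 degrees) at 64 px/deg.
#' @param freq_exponent Across-scale weighting exponent.
#' @return A `mir_response` (response map in model units, same size as the
#'   canvas, with the canvas geometry attached).
#' @export
odog <- function(image, n_orient = 6L, n_scales = 7L,
                 sigma_px = 3 * 2^(0:6), freq_exponent = 0.1) {
  if (!all(is.finite(image))) stop("non-finite values in input image")
  stopifnot(length(sigma_px) == n_scales)
  H <- nrow(image); W <- ncol(image)
  Fimg <- stats::fft(unclass_matrix(image))
  fr <- fft_freq(H); fc <- fft_freq(W)
  U <- matrix(fc, H, W, byrow = TRUE)   # cycles/px along columns (x)
  V <- matrix(fr, H, W)                 # along rows (y)
  w <- (1 / sigma_px)^freq_exponent
  w <- w / sum(w)
  out <- matrix(0, H, W)
  for (o in seq_len(n_orient)) {
    th <- (o - 1) * pi / n_orient
    Ur <- U * cos(th) + V * sin(th)     # across the filter axis
    Vr <- -U * sin(th) + V * cos(th)    # along the filter axis
    Ur2 <- Ur^2; Vr2 <- Vr^2
    Fsum <- matrix(0, H, W)
    for (k in seq_len(n_scales)) {
      s2 <- sigma_px[k]^2
      centre <- exp(-2 * pi^2 * s2 * (Ur2 + Vr2))
      surround <- exp(-2 * pi^2 * s2 * (Ur2 + 4 * Vr2))
      Fsum <- Fsum + w[k] * (centre - surround)
    }
    resp <- Re(stats::fft(Fimg * Fsum, inverse = TRUE)) / (H * W)
    rms <- sqrt(mean(resp^2))
    if (rms > 0) out <- out + resp / rms
  }
  as_response(out, image, "odog")
}

#' Linear high-pass brightness model
#'
#' The image minus its local mean over a square window. The standard
#' configuration uses a 96 px window on the 512 px stimulus, i.e. the
#' window covers a 3 x 3 cell region of the 16-cell grid. `filter_width = 1`
#' returns an all-zero map (the image minus itself).
#'
#' @param image A [mir_upsample()] canvas.
#' @param filter_width Odd box width in pixels.
#' @return A `mir_response`.
#' @export
highpass <- function(image, filter_width = 96L) {
  if (filter_width > min(dim(image))) stop("filter wider than the image")
  stopifnot(filter_width >= 1)
  resp <- unclass_matrix(image) - box_mean(unclass_matrix(image), filter_width)
  as_response(resp, image, "highpass")
}

#' Multiscale ratio-propagation retinex (McCann-style)
#'
#' Coarse-to-fine pyramid (factor 2). At each scale the lightness estimate
#' is updated `n_iterations` times by the ratio-product-reset-average rule
#' over the 8 neighbour directions: a neighbour's estimate is carried over
#' the local luminance ratio, clipped at the scale maximum (reset), and
#' averaged into the current estimate. The result is upsampled
#' progressively and returned in linear units relative to the image
#' maximum.
#'
#' @param image A [mir_upsample()] canvas (positive luminance).
#' @param n_iterations Updates per scale (default 4).
#' @return A `mir_response` with values in (0, 1].
#' @export
retinex_mccann <- function(image, n_iterations = 4L) {
  if (any(image <= 0)) stop("retinex requires strictly positive luminance")
  stopifnot(n_iterations >= 1)
  l <- log10(unclass_matrix(image) / max(image))
  pyr <- list(l)
  while (min(dim(pyr[[length(pyr)]])) > 16) {
    pyr[[length(pyr) + 1L]] <- halve(pyr[[length(pyr)]])
  }
  op <- matrix(0, nrow(pyr[[length(pyr)]]), ncol(pyr[[length(pyr)]]))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (lev in rev(seq_along(pyr))) {
    ll <- pyr[[lev]]
    if (!all(dim(op) == dim(ll))) op <- double_size(op, dim(ll))
    for (it in seq_len(n_iterations)) {
      for (sh in shifts) {
        cand <- shift_mat(op, sh) + ll - shift_mat(ll, sh)
        cand <- pmin(cand, 0)           # reset: estimates capped at maximum
        op <- (op + cand) / 2
      }
    }
  }
  as_response(10^op, image, "retinex")
}

# ---- shared helpers -------------------------------------------------------

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

fft_freq <- function(n) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  k[seq_len(n)]
}

box_mean <- function(m, width) {
  half <- (width - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  cs <- cbind(0, t(apply(rbind(0, apply(m, 2, cumsum)), 1, cumsum)))
  r0 <- pmax(0L, seq_len(H) - half - 1L); r1 <- pmin(H, seq_len(H) + half)
  c0 <- pmax(0L, seq_len(W) - half - 1L); c1 <- pmin(W, seq_len(W) + half)
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    a <- cs[r1 + 1L, c1[j] + 1L] - cs[r0 + 1L, c1[j] + 1L] -
      cs[r1 + 1L, c0[j] + 1L] + cs[r0 + 1L, c0[j] + 1L]
    out[, j] <- a / ((r1 - r0) * (c1[j] - c0[j]))
  }
  out
}

halve <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  (m[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(2, W, 2), drop = FALSE]) / 4
}

double_size <- function(m, target_dim) {
  big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2),
           drop = FALSE]
  big[seq_len(target_dim[1]), seq_len(target_dim[2]), drop = FALSE]
}

shift_mat <- function(m, sh) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - sh[1], 1L), H)
  ci <- pmin(pmax(seq_len(W) - sh[2], 1L), W)
  m[ri, ci, drop = FALSE]
}

as_response <- function(resp, canvas, model) {
  structure(resp, row_off = attr(canvas, "row_off"),
            col_off = attr(canvas, "col_off"),
            factor = attr(canvas, "factor"),
            grid_dim = attr(canvas, "grid_dim"),
            model = model, class = c("mir_response_full", "matrix", "array"))
}

#' Run a model on a catalogued stimulus
#'
#' Convenience wrapper: renders the stimulus, hands it to the requested
#' model (the decomposition model directly on the grid; the three
#' comparison models on the standard upsampled mean-padded canvas) and
#' returns the 16 x 16 response read-out plus target means.
#'
#' @param model `"mir"`, `"odog"`, `"highpass"` or `"retinex"`.
#' @param stimulus A `mir_stimulus` or catalogue name.
#' @param params [mir_params()] for the decomposition model.
#' @param ... Extra arguments for the model function.
#' @return A `mir_response` object: list with `model`, `stimulus`, `map`
#'   (matrix in the stimulus frame; reflectance for `"mir"`), and `scale`
#'   (the map range, used for relative dead-bands).
#' @export
run_model <- function(model = c("mir", "odog", "highpass", "retinex"),
                      stimulus, params = mir_params(), ...) {
  model <- match.arg(model)
  if (is.character(stimulus)) stimulus <- mir_stimulus(stimulus)
  if (model == "mir") {
    fit <- mir_decompose(stimulus, params, ...)
    map <- fit$reflectance
  } else {
    canvas <- mir_upsample(mir_render(stimulus), factor = 32L,
                           canvas = dim(stimulus$reflectance) * 32L + 512L)
    full <- switch(model,
                   odog = odog(canvas, ...),
                   highpass = highpass(canvas, ...),
                   retinex = retinex_mccann(canvas, ...))
    map <- mir_downsample(full)
  }
  structure(list(model = model, stimulus = stimulus, map = map,
                 scale = diff(range(map))),
            class = "mir_response")
}

#' @export
print.mir_response <- function(x, ...) {
  cat(sprintf("%s response to '%s': %d x %d map, range %.4g to %.4g\n",
              x$model, x$stimulus$name, nrow(x$map), ncol(x$map),
              min(x$map), max(x$map)))
  invisible(x)
}
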