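# Resolution bridging between the 16x16 grid world and the pixel-based
# comparison models: block replication up to filter resolution on a
# mean-padded canvas, and block averaging back down.

#' Upsample a luminance grid for filter-based models
#'
#' Nearest-neighbour block replication (the grids are piecewise constant),
#' centred in a larger canvas whose remaining pixels are set to the mean
#' luminance of the stimulus. The standard configuration maps a 16 x 16
#' stimulus to 512 x 512 pixels inside a 1024 x 1024 canvas, i.e. the
#' stimulus subtends half the modelled field; 512 pixels represent 8 degrees
#' of visual angle.
#'
#' @param grid Luminance matrix.
#' @param factor Integer block replication factor (>= 1).
#' @param canvas `c(H, W)` canvas size in pixels; must fit the upsampled
#'   stimulus.
#' @return A `mir_canvas` object: the canvas matrix plus placement
#'   attributes (`row_off`, `col_off`, `factor`, `grid_dim`) used by
#'   [mir_downsample()].
#' @examples
#' cv <- mir_upsample(matrix(1:4, 2, 2), factor = 2, canvas = c(8, 8))
#' dim(cv)
#' @export
mir_upsample <- function(grid, factor = 32L,
                         canvas = c(1024L, 1024L)) {
  stopifnot(is.matrix(grid), factor >= 1)
  factor <- as.integer(factor)
  H <- nrow(grid) * factor; W <- ncol(grid) * factor
  if (canvas[1] < H || canvas[2] < W) {
    stop("canvas smaller than the upsampled stimulus")
  }
  big <- grid[rep(seq_len(nrow(grid)), each = factor),
              rep(seq_len(ncol(grid)), each = factor), drop = FALSE]
  out <- matrix(mean(grid), canvas[1], canvas[2])
  row_off <- (canvas[1] - H) %/% 2L
  col_off <- (canvas[2] - W) %/% 2L
  out[row_off + seq_len(H), col_off + seq_len(W)] <- big
  structure(out, row_off = row_off, col_off = col_off, factor = factor,
            grid_dim = dim(grid), class = c("mir_canvas", "matrix", "array"))
}

#' Downsample a model response back to the stimulus grid
#'
#' Block means over the canvas region corresponding to each original grid
#' cell; the mean-luminance padding is excluded. `map` may be a raw response
#' matrix of the same size as the canvas, in which case the canvas geometry
#' must be supplied via `geometry`.
#'
#' @param map Response matrix (same dimensions as the canvas it came from).
#' @param geometry A `mir_canvas` (or any object carrying the placement
#'   attributes) describing where the stimulus sits; defaults to `map`
#'   itself.
#' @return Matrix with the original grid dimensions.
#' @export
mir_downsample <- function(map, geometry = map) {
  fac <- attr(geometry, "factor")
  gd <- attr(geometry, "grid_dim")
  ro <- attr(geometry, "row_off"); co <- attr(geometry, "col_off")
  if (is.null(fac) || is.null(gd)) {
    stop("no canvas geometry available; pass the mir_upsample() result")
  }
  if (nrow(map) < ro + gd[1] * fac || ncol(map) < co + gd[2] * fac) {
    stop("response map smaller than the stimulus region")
  }
  out <- matrix(0, gd[1], gd[2])
  for (i in seq_len(gd[1])) for (j in seq_len(gd[2])) {
    rows <- ro + ((i - 1L) * fac + 1L):(i * fac)
    colz <- co + ((j - 1L) * fac + 1L):(j * fac)
    out[i, j] <- mean(map[rows, colz])
  }
  out
}
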