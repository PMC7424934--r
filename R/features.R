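# Stimulus feature extraction: uniform regions, luminance edges, X-junctions.
# All features are computed from the observed luminance image and condition
# the potential functions of the hidden-layer model.

#' Segment a luminance grid into uniform regions
#'
#' Regions are 4-connected components of cells with equal luminance (within
#' a relative tolerance). The grid stimuli are piecewise constant by
#' construction, so the default tolerance is tight.
#'
#' @param grid Luminance matrix (cd/m^2, positive).
#' @param tol Relative luminance tolerance for equality.
#' @return A list with `labels` (integer matrix, components numbered from 1
#'   in raster order of first visit) and `n_regions`.
#' @examples
#' segment_regions(matrix(1, 4, 4))$n_regions  # 1
#' @export
segment_regions <- function(grid, tol = 1e-6) {
  stopifnot(is.matrix(grid), all(grid > 0), tol >= 0)
  H <- nrow(grid); W <- ncol(grid)
  labels <- matrix(0L, H, W)
  nxt <- 0L
  eq <- function(a, b) abs(a - b) <= tol * pmax(a, b)
  for (start in seq_len(H * W)) {
    if (labels[[start]] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[[start]] <- nxt
    while (length(queue)) {
      cell <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (cell - 1L) %% H + 1L
      c <- (cell - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        nb <- (cc - 1L) * H + rr
        if (labels[[nb]] == 0L && eq(grid[[cell]], grid[[nb]])) {
          labels[[nb]] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(labels = labels, n_regions = nxt)
}

#' Detect luminance edges between adjacent cells
#'
#' Flags every horizontally or vertically adjacent cell pair whose absolute
#' log10 luminance difference exceeds `tol`, and stores the magnitudes.
#'
#' @param grid Luminance matrix.
#' @param tol Log10 contrast threshold.
#' @return A list with `h_contrast` (H x (W-1) contrasts between
#'   horizontally adjacent cells), `v_contrast` ((H-1) x W), matching
#'   logical `h_edge`/`v_edge` flags, and `n_edges`.
#' @export
detect_edges <- function(grid, tol = 1e-9) {
  stopifnot(is.matrix(grid), all(grid > 0), tol >= 0)
  lg <- log10(grid)
  H <- nrow(grid); W <- ncol(grid)
  h_contrast <- abs(lg[, -1, drop = FALSE] - lg[, -W, drop = FALSE])
  v_contrast <- abs(lg[-1, , drop = FALSE] - lg[-H, , drop = FALSE])
  list(h_contrast = h_contrast, v_contrast = v_contrast,
       h_edge = h_contrast > tol, v_edge = v_contrast > tol,
       n_edges = sum(h_contrast > tol) + sum(v_contrast > tol))
}

#' Detect X-junctions in 2x2 patches
#'
#' A 2x2 patch whose luminance ratios agree across a candidate dividing
#' line (top/bottom ratios equal across a vertical line, or left/right
#' ratios equal across a horizontal line) is an X-junction: the photometric
#' signature of a lighting or transparency border crossing a reflectance
#' edge. The score is graded from 1 (exactly ratio-consistent) to 0 (log
#' ratio mismatch at or beyond `ratio_tol`), and is 0 whenever any
#' luminances are equal across the candidate line.
#'
#' @param grid Luminance matrix.
#' @param ratio_tol Log10 mismatch at which the evidence score reaches 0.
#' @return A list with matrices `score` ((H-1) x (W-1), in `[0, 1]`) and
#'   `orientation` (`"vertical"`, `"horizontal"` or `"none"`; the
#'   orientation of the implied lighting edge).
#' @examples
#' g <- matrix(c(10, 30, 20, 60), 2, 2)   # 10*60 == 20*30: X-junction
#' detect_xjunctions(g)$score[1, 1]
#' @export
detect_xjunctions <- function(grid, ratio_tol = 0.02) {
  stopifnot(is.matrix(grid), all(grid > 0), ratio_tol >= 0)
  lg <- log10(grid)
  H <- nrow(grid); W <- ncol(grid)
  score <- matrix(0, H - 1, W - 1)
  orientation <- matrix("none", H - 1, W - 1)
  for (i in seq_len(H - 1)) for (j in seq_len(W - 1)) {
    a <- lg[i, j]; b <- lg[i, j + 1]; c <- lg[i + 1, j]; d <- lg[i + 1, j + 1]
    mism <- abs(a - b - c + d)
    s <- if (ratio_tol > 0) max(0, 1 - mism / ratio_tol) else as.numeric(mism == 0)
    # a junction is a crossing of two edges: all four adjacent pairs differ
    # (a patch with two equal rows or columns is a plain straight edge)
    crossing <- a != b && c != d && a != c && b != d
    if (crossing && s > 0) {
      score[i, j] <- s
      # ratio consistency is symmetric in the two readings; report the
      # direction with the larger luminance step as the reflectance edge
      # and the other as the implied lighting edge
      vstep <- (abs(a - b) + abs(c - d)) / 2
      hstep <- (abs(a - c) + abs(b - d)) / 2
      orientation[i, j] <- if (abs(vstep - hstep) < 1e-12) "both"
        else if (vstep < hstep) "vertical" else "horizontal"
    }
  }
  list(score = score, orientation = orientation)
}
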