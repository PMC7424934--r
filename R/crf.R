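# Conditional random field assembly.
#
# One hidden variable per cell holds a discretised log10 illuminance level;
# reflectance is tied to it deterministically as r = L / e, so the generative
# constraint (luminance = illuminance x reflectance) holds exactly for every
# assignment. One factor per interior 2x2 patch carries all local costs:
#
#   * per-cell terms: reflectance-band barrier (+ glow surcharge) and the
#     log illuminance prior, the latter shared out over the cell's uniform
#     luminance region so each region is charged once;
#   * per-pair terms: squared log illuminance steps and truncated squared
#     reflectance steps, inflated where no luminance edge exists, discounted
#     at X-junctions, and shared out over straight same-region-pair boundary
#     segments so a coherent lighting boundary is charged once;
#   * a corner penalty when the within-patch illuminance step pattern is
#     L-shaped (lighting boundaries tend to be straight).
#
# Per-cell and per-edge quantities are divided by the number of patches that
# contain them, so every term enters the total energy exactly once.

#' Per-cell reflectance cost
#'
#' Zero inside the plausible matte band, a quadratic log-barrier outside it,
#' and a fixed surcharge above reflectance 1 so that self-luminous ("glow")
#' interpretations are representable at a finite price.
#'
#' @param r Reflectance fraction(s), positive.
#' @param params A [mir_params()] object.
#' @return Cost value(s).
#' @examples
#' reflectance_cost(0.5) # 0: inside the band
#' @export
reflectance_cost <- function(r, params = mir_params()) {
  if (any(r <= 0)) stop("reflectance must be positive")
  lo <- params$r_band[1]; hi <- params$r_band[2]
  cost <- ifelse(r > hi, params$w_band * (log10(r / hi))^2,
          ifelse(r < lo, params$w_band * (log10(lo / r))^2, 0))
  cost + params$w_glow * (r > 1)
}

#' Per-region illuminance prior cost
#'
#' A logarithmic cost on illuminance: low illuminances are more probable
#' than high ones. Evaluated once per uniform luminance region; this is the
#' pressure that drives the highest luminance in a lighting framework
#' towards a white reflectance.
#'
#' @param e Illuminance (model lux), positive.
#' @param params A [mir_params()] object.
#' @return Cost value(s): `prior_slope * log10(e)`.
#' @export
illuminance_prior_cost <- function(e, params = mir_params()) {
  if (any(e <= 0)) stop("illuminance must be positive")
  params$prior_slope * log10(e)
}

# Number of interior patches containing each cell / edge.
patch_mult_cell <- function(H, W) {
  rm <- pmin(seq_len(H), H - 1L, seq(H, 1L), 2L)
  cm <- pmin(seq_len(W), W - 1L, seq(W, 1L), 2L)
  outer(rm, cm)
}

# Facet decomposition: maximal straight runs of flagged edges that separate
# the same unordered region pair. Returns, per edge, the summed patch
# multiplicity of its facet (the divisor that charges a facet once).
facet_weights <- function(labels, edges) {
  H <- nrow(labels); W <- ncol(labels)
  h_T <- matrix(NA_real_, H, W - 1)   # edges between (r,c) and (r,c+1)
  v_T <- matrix(NA_real_, H - 1, W)
  h_mult <- outer(pmin(seq_len(H), H - 1L, seq(H, 1L), 2L), rep(1L, W - 1))
  v_mult <- outer(rep(1L, H - 1), pmin(seq_len(W), W - 1L, seq(W, 1L), 2L))
  if (W >= 2) {
    for (c in seq_len(W - 1)) {       # vertical boundary lines: runs over rows
      r <- 1L
      while (r <= H) {
        if (!edges$h_edge[r, c]) { r <- r + 1L; next }
        pair <- sort(c(labels[r, c], labels[r, c + 1]))
        r2 <- r
        while (r2 + 1L <= H && edges$h_edge[r2 + 1L, c] &&
               identical(sort(c(labels[r2 + 1L, c], labels[r2 + 1L, c + 1])), pair)) {
          r2 <- r2 + 1L
        }
        h_T[r:r2, c] <- sum(h_mult[r:r2, c])
        r <- r2 + 1L
      }
    }
  }
  if (H >= 2) {
    for (r in seq_len(H - 1)) {       # horizontal boundary lines: runs over cols
      c <- 1L
      while (c <= W) {
        if (!edges$v_edge[r, c]) { c <- c + 1L; next }
        pair <- sort(c(labels[r, c], labels[r + 1, c]))
        c2 <- c
        while (c2 + 1L <= W && edges$v_edge[r, c2 + 1L] &&
               identical(sort(c(labels[r, c2 + 1L], labels[r + 1, c2 + 1L])), pair)) {
          c2 <- c2 + 1L
        }
        v_T[r, c:c2] <- sum(v_mult[r, c:c2])
        c <- c2 + 1L
      }
    }
  }
  list(h_T = h_T, v_T = v_T, h_mult = h_mult, v_mult = v_mult)
}

#' Build the patch-factor graph for a luminance grid
#'
#' Extracts uniform regions, luminance edges and X-junctions, chooses a
#' per-stimulus state space of log10 illuminance levels wide enough for
#' every cell to express reflectances across `params$r_cover`, and packs the
#' per-patch cost tables used by the inference routines.
#'
#' @param grid Luminance matrix (cd/m^2) or a `mir_stimulus` (rendered with
#'   the default calibration).
#' @param params A [mir_params()] object.
#' @return A `mir_crf` object (list with the grid, levels, features, packed
#'   tables and parameters).
#' @examples
#' crf <- mir_crf(mir_render(matrix(c(1, 1, 2, 2), 2, 2) * 0.3))
#' length(crf$levels)
#' @export
mir_crf <- function(grid, params = mir_params()) {
  if (inherits(grid, "mir_stimulus")) grid <- mir_render(grid)
  stopifnot(is.matrix(grid), all(grid > 0), all(is.finite(grid)))
  H <- nrow(grid); W <- ncol(grid)
  if (H < 2 || W < 2) stop("grid must be at least 2 x 2")
  lo <- log10(max(grid) / params$r_cover[2]) - params$range_pad
  hi <- log10(min(grid) / params$r_cover[1])
  if (lo >= hi) {
    stop("luminance range too wide for the state space to cover the reflectance band")
  }
  levels <- seq(lo, hi, length.out = params$n_levels)
  logL <- log10(grid)
  seg <- segment_regions(grid, params$lum_tol)
  edges <- detect_edges(grid, tol = 1e-9)
  xj <- detect_xjunctions(grid, params$xj_tol)
  fw <- facet_weights(seg$labels, edges)
  region_size <- tabulate(seg$labels, seg$n_regions)

  mult_cell <- patch_mult_cell(H, W)
  n <- params$n_levels
  # unary tables: n x (H*W), already divided by cell multiplicity
  unary <- matrix(0, n, H * W)
  for (cell in seq_len(H * W)) {
    r_states <- grid[[cell]] / 10^levels
    cost <- reflectance_cost(r_states, params) +
      params$prior_slope * levels / region_size[seg$labels[[cell]]]
    unary[, cell] <- cost / mult_cell[[cell]]
  }
  De <- outer(levels, levels, "-")            # e(first) - e(second)
  De2 <- De^2
  tr2 <- params$refl_trunc^2
  nP <- (H - 1L) * (W - 1L)
  tables <- array(0, dim = c(n, n, 4L, nP))
  pair_cost <- function(dL, scale, xj_mult) {
    # dL: signed log10 luminance (first minus second); reflectance step is
    # dL - De under the generative tie r = L / e.
    illum <- params$w_illum * xj_mult * De2
    refl <- params$w_refl * pmin((dL - De)^2, tr2)
    scale * (illum + refl)
  }
  for (j in seq_len(W - 1)) for (i in seq_len(H - 1)) {
    p <- (j - 1L) * (H - 1L) + i
    sc <- xj$score[i, j]; ori <- xj$orientation[i, j]
    m_v <- if (ori %in% c("vertical", "both"))
      1 - (1 - params$xj_discount) * sc else 1
    m_h <- if (ori %in% c("horizontal", "both"))
      1 - (1 - params$xj_discount) * sc else 1
    # slot 1: AB, cells (i,j)-(i,j+1): h edge [i, j]
    # slot 2: CD, cells (i+1,j)-(i+1,j+1): h edge [i+1, j]
    # slot 3: AC, cells (i,j)-(i+1,j): v edge [i, j]
    # slot 4: BD, cells (i,j+1)-(i+1,j+1): v edge [i, j+1]
    for (slot in 1:4) {
      if (slot <= 2L) {
        er <- if (slot == 1L) i else i + 1L
        flagged <- edges$h_edge[er, j]
        dL <- logL[er, j] - logL[er, j + 1]
        scale <- if (flagged) 1 / fw$h_T[er, j] else
          params$no_edge_mult / fw$h_mult[er, j]
        xm <- if (flagged) m_v else 1
      } else {
        ec <- if (slot == 3L) j else j + 1L
        flagged <- edges$v_edge[i, ec]
        dL <- logL[i, ec] - logL[i + 1, ec]
        scale <- if (flagged) 1 / fw$v_T[i, ec] else
          params$no_edge_mult / fw$v_mult[i, ec]
        xm <- if (flagged) m_h else 1
      }
      tables[, , slot, p] <- pair_cost(dL, scale, xm)
    }
  }

  structure(
    list(grid = grid, logL = logL, H = H, W = W, levels = levels,
         regions = seg, edges = edges, xjunctions = xj,
         unary = unary, tables = tables, w_corner = params$w_corner,
         params = params),
    class = "mir_crf"
  )
}

#' @export
print.mir_crf <- function(x, ...) {
  cat(sprintf("Patch CRF: %d x %d cells, %d levels (%.3f log10 step), %d patch factors, %d regions\n",
              x$H, x$W, length(x$levels), x$levels[2] - x$levels[1],
              (x$H - 1) * (x$W - 1), x$regions$n_regions))
  invisible(x)
}

#' Evaluate one patch potential
#'
#' Returns the cost a single 2x2 patch factor assigns to four state indices
#' (A = top-left, B = top-right, C = bottom-left, D = bottom-right),
#' including the corner penalty. The total energy of an assignment is the
#' sum of this quantity over all patches.
#'
#' @param crf A `mir_crf` object.
#' @param i,j Patch top-left cell coordinates (1-based).
#' @param states Integer vector of 4 state indices (A, B, C, D).
#' @return Cost scalar.
#' @export
patch_potential <- function(crf, i, j, states) {
  stopifnot(inherits(crf, "mir_crf"), length(states) == 4,
            all(states >= 1), all(states <= length(crf$levels)),
            i >= 1, i <= crf$H - 1, j >= 1, j <= crf$W - 1)
  p <- (j - 1L) * (crf$H - 1L) + i
  A <- states[1]; B <- states[2]; C <- states[3]; D <- states[4]
  cellidx <- function(r, c) (c - 1L) * crf$H + r
  u <- crf$unary[A, cellidx(i, j)] + crf$unary[B, cellidx(i, j + 1L)] +
    crf$unary[C, cellidx(i + 1L, j)] + crf$unary[D, cellidx(i + 1L, j + 1L)]
  pw <- crf$tables[A, B, 1L, p] + crf$tables[C, D, 2L, p] +
    crf$tables[A, C, 3L, p] + crf$tables[B, D, 4L, p]
  hstep <- (A != B) || (C != D)
  vstep <- (A != C) || (B != D)
  u + pw + if (hstep && vstep) crf$w_corner else 0
}

#' Total energy of a full assignment
#'
#' @param crf A `mir_crf` object.
#' @param states Integer matrix (H x W) of state indices.
#' @return The energy (sum over patch factors), the exponent of the Gibbs
#'   distribution.
#' @export
crf_energy <- function(crf, states) {
  stopifnot(inherits(crf, "mir_crf"), is.matrix(states),
            nrow(states) == crf$H, ncol(states) == crf$W)
  mir_energy_cpp(crf$tables, crf$unary, as.integer(states) - 1L,
                 crf$H, crf$W, length(crf$levels), crf$w_corner)
}
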