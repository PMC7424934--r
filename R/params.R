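#' Model parameters for the illuminance/reflectance CRF
#'
#' Collects every tunable weight of the lightness model in one place. The
#' model expresses seven qualitative assumptions about lighting and surfaces
#' as local costs on 2x2 patches of a discretised log-illuminance field; the
#' weights below set the exchange rate between them.
#'
#' @param n_levels Number of discrete log10-illuminance levels per stimulus.
#'   The level grid is uniform and spans the range needed for every cell to
#'   realise reflectances in `r_cover`.
#' @param r_band Reflectance band treated as free of cost, as fractions
#'   (matte surfaces span roughly 3% to 90% reflectance).
#' @param r_cover Reflectance range the state space must be able to express
#'   at every cell (extends above 1 so self-luminous "glow" percepts are
#'   representable).
#' @param range_pad Extra log10 depth added below the dimmest level implied
#'   by `r_cover`, so that shadowed regions can be discounted fully even
#'   when the scene's brightest cell pins the nominal floor.
#' @param w_band Weight of the quadratic log-barrier outside `r_band`, per
#'   squared log10 unit, charged per cell.
#' @param w_glow Fixed additional cost per cell for reflectance above 1.0
#'   (glow is representable but at a price).
#' @param prior_slope Weight of the logarithmic cost on illuminance
#'   (low illuminances are more probable than high ones), charged once per
#'   uniform luminance region.
#' @param w_illum Weight of the squared log10 illuminance step across an
#'   edge, charged once per straight same-region-pair boundary segment.
#' @param w_refl Weight of the (truncated) squared log10 reflectance step
#'   across an edge; reflectance edges are common and therefore much cheaper
#'   than illuminance edges.
#' @param refl_trunc Truncation point (log10 units) of the reflectance edge
#'   cost; beyond this a reflectance edge costs a constant, so large
#'   reflectance steps are not hedged into partial lighting boundaries.
#' @param no_edge_mult Multiplier on illuminance/reflectance step costs at
#'   cell pairs with no luminance edge (hidden edges should coincide with
#'   image edges).
#' @param xj_discount Multiplier (< 1) on the illuminance step cost inside a
#'   patch whose luminance pattern is ratio-consistent (an X-junction);
#'   X-junctions are strong evidence for a lighting boundary.
#' @param xj_tol Log10 tolerance of the graded ratio-consistency score.
#' @param w_corner Penalty per patch whose illuminance-step pattern is
#'   L-shaped (lighting boundaries tend to be straight).
#' @param seg_threshold Minimum log10 illuminance boundary step for a region
#'   to count as a strongly segmented lighting framework (used by the
#'   highest-luminance statistics).
#' @param lum_tol Relative tolerance for luminance equality when segmenting
#'   uniform regions and flagging edges (stimuli are exact by construction).
#' @param damping Message damping of max-sum belief propagation, in `[0, 1)`.
#' @param max_iter Maximum number of synchronous message-passing rounds.
#' @param bp_tol Max-norm message change below which propagation stops.
#' @param polish If `TRUE`, the decoded state is refined by single-cell
#'   coordinate descent until it is a local energy minimum.
#'
#' @return An object of class `mir_params` (a validated list).
#' @examples
#' p <- mir_params()
#' p$n_levels
#' @export
mir_params <- function(n_levels = 45L,
                       r_band = c(0.03, 0.90),
                       r_cover = c(0.02, 1.20),
                       range_pad = 0.3,
                       w_band = 20,
                       w_glow = 2,
                       prior_slope = 0.5,
                       w_illum = 25,
                       w_refl = 1,
                       refl_trunc = 0.28,
                       no_edge_mult = 1.5,
                       xj_discount = 0.02,
                       xj_tol = 0.02,
                       w_corner = 4,
                       seg_threshold = 0.15,
                       lum_tol = 1e-6,
                       damping = 0.5,
                       max_iter = 300L,
                       bp_tol = 1e-5,
                       polish = TRUE) {
  p <- list(
    n_levels = as.integer(n_levels), r_band = as.numeric(r_band),
    r_cover = as.numeric(r_cover), range_pad = range_pad,
    w_band = w_band, w_glow = w_glow,
    prior_slope = prior_slope, w_illum = w_illum, w_refl = w_refl,
    refl_trunc = refl_trunc, no_edge_mult = no_edge_mult,
    xj_discount = xj_discount, xj_tol = xj_tol, w_corner = w_corner,
    seg_threshold = seg_threshold, lum_tol = lum_tol, damping = damping,
    max_iter = as.integer(max_iter), bp_tol = bp_tol, polish = isTRUE(polish)
  )
  validate_mir_params(p)
  class(p) <- "mir_params"
  p
}

validate_mir_params <- function(p) {
  stopifnot(
    p$n_levels >= 2L,
    length(p$r_band) == 2L, p$r_band[1] > 0, p$r_band[2] > p$r_band[1],
    length(p$r_cover) == 2L, p$r_cover[1] > 0, p$r_cover[2] > p$r_cover[1],
    p$r_cover[1] <= p$r_band[1], p$r_cover[2] >= p$r_band[2]
  )
  wts <- c(p$w_band, p$w_glow, p$prior_slope, p$w_illum, p$w_refl,
           p$range_pad, p$refl_trunc, p$no_edge_mult, p$xj_discount, p$xj_tol,
           p$w_corner, p$seg_threshold, p$lum_tol)
  if (any(!is.finite(wts)) || any(wts < 0)) {
    stop("all mir_params weights must be finite and non-negative")
  }
  stopifnot(p$damping >= 0, p$damping < 1, p$max_iter >= 1L, p$bp_tol > 0)
  invisible(p)
}

#' @export
print.mir_params <- function(x, ...) {
  cat("Illuminance/reflectance CRF parameters\n")
  cat(sprintf("  state space : %d log10-illuminance levels (reflectance cover %.2f-%.2f)\n",
              x$n_levels, x$r_cover[1], x$r_cover[2]))
  cat(sprintf("  reflectance : free band %.2f-%.2f, barrier %g, glow surcharge %g\n",
              x$r_band[1], x$r_band[2], x$w_band, x$w_glow))
  cat(sprintf("  priors      : illuminance slope %g per region\n", x$prior_slope))
  cat(sprintf("  edges       : illuminance %g, reflectance %g (trunc %g), no-edge x%g, X-junction x%g, corner %g\n",
              x$w_illum, x$w_refl, x$refl_trunc, x$no_edge_mult,
              x$xj_discount, x$w_corner))
  cat(sprintf("  inference   : damping %g, max %d rounds, tol %g, polish %s\n",
              x$damping, x$max_iter, x$bp_tol, x$polish))
  invisible(x)
}

#' Serialise / restore model parameters
#'
#' Parameters round-trip through YAML so a configuration can be stored next
#' to results; [params_hash()] gives a short digest used in provenance
#' records.
#'
#' @param params A [mir_params()] object.
#' @param path File to write to or read from.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `mir_params` object; `params_hash` a character scalar.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mir_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  do.call(mir_params, p)
}

#' @rdname write_params
#' @export
params_hash <- function(params) {
  stopifnot(inherits(params, "mir_params"))
  txt <- paste(
    vapply(unclass(params), function(v) paste(format(v, digits = 15), collapse = ","),
           character(1)),
    collapse = ";"
  )
  # small rolling hash; avoids a digest dependency for a provenance tag
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
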