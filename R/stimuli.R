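# Stimulus battery: 16x16 grid renditions of classic lightness illusions.
#
# Reflectances follow a small palette read off the printed figures
# (black ~0.10, dark grays 0.15-0.30, mid grays 0.40-0.55, paper white 0.82);
# within every figure the two judged target regions have exactly equal
# reflectance, which is the constraint the illusions depend on. "Shadowed"
# areas are emulated by scaling printed reflectance by a transmittance
# factor, which preserves luminance ratios across the shadow border and so
# creates the X-junctions several of the figures rely on.

PAPER_WHITE <- 0.82
WHITE_LUMINANCE <- 89           # cd/m^2 of paper white under the room lighting
DEFAULT_ILLUMINANCE <- WHITE_LUMINANCE / PAPER_WHITE

new_stimulus <- function(name, reflectance, green = NULL, red = NULL,
                         expected = "green", scorable = TRUE,
                         illum_profile = NULL, mirrored = FALSE) {
  stopifnot(is.matrix(reflectance), all(reflectance > 0),
            all(reflectance <= 1.2))
  if (!is.null(green)) {
    stopifnot(is.matrix(green), ncol(green) == 2,
              is.matrix(red), ncol(red) == 2)
    idx_g <- cbind(green[, 1], green[, 2])
    idx_r <- cbind(red[, 1], red[, 2])
    if (any(idx_g[, 1] < 1 | idx_g[, 1] > nrow(reflectance) |
            idx_g[, 2] < 1 | idx_g[, 2] > ncol(reflectance)) ||
        any(idx_r[, 1] < 1 | idx_r[, 1] > nrow(reflectance) |
            idx_r[, 2] < 1 | idx_r[, 2] > ncol(reflectance))) {
      stop("target cells outside the grid")
    }
    key <- function(m) paste(m[, 1], m[, 2])
    if (length(intersect(key(green), key(red)))) {
      stop("green and red target sets overlap")
    }
    rg <- reflectance[idx_g]; rr <- reflectance[idx_r]
    if (max(abs(rg - mean(rg))) > 1e-12 || max(abs(rr - mean(rr))) > 1e-12 ||
        abs(mean(rg) - mean(rr)) > 1e-12) {
      stop(sprintf("targets of '%s' are not isoluminant", name))
    }
  }
  structure(
    list(name = name, reflectance = reflectance,
         targets = if (is.null(green)) NULL else
           list(green = unname(green), red = unname(red)),
         expected = expected, scorable = scorable,
         illum_profile = illum_profile, mirrored = mirrored),
    class = "mir_stimulus"
  )
}

cells <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))
}

# ---- individual generators ------------------------------------------------

# Argyle family: vertical strips of width 4 alternately plain and "shadowed"
# (x0.55), textured with one-row horizontal bands so that every patch on a
# strip border is an X-junction. Targets are mid-gray 2x2 patches of
# identical reflectance, one inside a shadowed strip, one inside a lit strip.
argyle_grid <- function(n_strips = 4L) {
  w <- 0.82; m <- 0.30; t <- 0.55
  W <- 4L * n_strips
  g <- matrix(0, 16, W)
  for (col in seq_len(W)) {
    strip <- (col - 1L) %/% 4L + 1L
    shade <- if (strip %% 2L == 0L) t else 1
    for (row in 1:16) {
      band_w <- row %% 2L == 1L                   # odd rows white-band
      g[row, col] <- (if (band_w) w else m) * shade
    }
  }
  g
}

stim_argyle <- function() {
  g <- argyle_grid(4L)
  g[7:8, 6:7] <- 0.30            # green: light diamond inside shadowed strip
  g[7:8, 10:11] <- 0.30          # red: same reflectance inside lit strip
  new_stimulus("argyle", g, cells(7:8, 6:7), cells(7:8, 10:11))
}

stim_long_range_argyle <- function() {
  g <- argyle_grid(6L)           # 16 x 24: targets several strips apart
  g[7:8, 6:7] <- 0.30
  g[7:8, 18:19] <- 0.30
  new_stimulus("long_range_argyle", g, cells(7:8, 6:7), cells(7:8, 18:19))
}

# Control: the outer bands of the shadowed strips revert to plain values, so
# the strip borders no longer run edge to edge and the ratio structure is
# broken; the targets and their immediate surrounds are unchanged.
stim_argyle_control <- function() {
  g <- argyle_grid(4L)
  for (strip_cols in list(5:8, 13:16)) {
    g[c(1:4, 13:16), strip_cols] <- g[c(1:4, 13:16), strip_cols] / 0.55
  }
  g[7:8, 6:7] <- 0.30
  g[7:8, 10:11] <- 0.30
  new_stimulus("argyle_control", g, cells(7:8, 6:7), cells(7:8, 10:11),
               expected = "none")
}

# First-experiment argyle variants: identical construction, but the top and
# bottom two rows are a uniform gray, so the strip boundaries stop short of
# the figure edge (weaker segmentation of the lighting frameworks).
cap_rows <- function(s, value = 0.41) {
  g <- s$reflectance
  g[c(1:2, 15:16), ] <- value
  new_stimulus(paste0(s$name, "_exp1"), g, s$targets$green, s$targets$red,
               expected = s$expected, scorable = s$scorable)
}

stim_argyle_exp1 <- function() cap_rows(stim_argyle())
stim_long_range_argyle_exp1 <- function() cap_rows(stim_long_range_argyle())
stim_argyle_control_exp1 <- function() cap_rows(stim_argyle_control())

# Koffka ring family. Background is split into a darker left and lighter
# right half; a mid-gray square annulus straddles the border. The connected
# ring blocks the lighting-boundary interpretation; breaking the ring at the
# border restores it; the Koffka-Adelson variant keeps the ring connected
# but adds ratio-consistent banding, giving X-junction evidence instead.
koffka_base <- function(banded = FALSE) {
  g <- matrix(0, 16, 16)
  for (row in 1:16) {
    if (banded) {
      # band contrast (2.28x) exceeds the left/right shadow ratio (2x), so
      # the ratio-consistent border reads as a vertical lighting edge
      lv <- if (row %% 2L == 1L) c(0.41, 0.82) else c(0.18, 0.36)
    } else {
      lv <- c(0.41, 0.82)
    }
    g[row, 1:8] <- lv[1]; g[row, 9:16] <- lv[2]
  }
  ring <- matrix(FALSE, 16, 16)
  ring[5:12, 5:12] <- TRUE
  ring[7:10, 7:10] <- FALSE
  g[ring] <- 0.55
  g
}

stim_koffka_connected <- function() {
  new_stimulus("koffka_connected", koffka_base(),
               cells(8:9, 5:6), cells(8:9, 11:12), expected = "none")
}

stim_koffka_broken <- function() {
  g <- koffka_base()
  g[c(5:6, 11:12), 8] <- 0.41    # gap: ring cells at the border revert to bg
  g[c(5:6, 11:12), 9] <- 0.82
  new_stimulus("koffka_broken", g, cells(8:9, 5:6), cells(8:9, 11:12))
}

stim_koffka_adelson <- function() {
  new_stimulus("koffka_adelson", koffka_base(banded = TRUE),
               cells(8:9, 5:6), cells(8:9, 11:12))
}

# White's illusion: a square-wave grating of full-height bars; equal gray
# patches sit on a dark and on a light bar. Human observers see the patch on
# the dark bar as lighter (assimilation).
stim_whites <- function() {
  g <- matrix(0, 16, 16)
  for (col in 1:16) {
    bar <- (col - 1L) %/% 2L
    g[, col] <- if (bar %% 2L == 0L) 0.10 else 0.82
  }
  g[7:10, 5:6] <- 0.40
  g[7:10, 11:12] <- 0.40
  new_stimulus("whites", g, cells(7:10, 5:6), cells(7:10, 11:12))
}

# Checkerboard assimilation: two equal grays replace single checks; the one
# whose four neighbours are white appears lighter.
stim_checkerboard <- function() {
  g <- matrix(0, 16, 16)
  for (row in 1:16) for (col in 1:16) {
    g[row, col] <- if ((row + col) %% 2L == 0L) 0.10 else 0.82
  }
  g[8, 4] <- 0.40                # green: replaces a dark check, white neighbours
  g[8, 13] <- 0.40               # red: replaces a light check, dark neighbours
  new_stimulus("checkerboard", g, cells(8, 4), cells(8, 13))
}

# Snake family: the argyle construction rotated to horizontal "shadow"
# strips with two-column texture bands. The control shifts the strip borders
# by one row in alternating column groups, so every long lighting boundary
# would need corners.
snake_values <- function(shadow_rows_for_group) {
  g <- matrix(0, 16, 16)
  for (col in 1:16) {
    band_w <- col %% 2L == 1L                     # one-column texture bands
    base <- if (band_w) 0.82 else 0.30
    group <- (col - 1L) %/% 4L + 1L
    shade_rows <- shadow_rows_for_group(group)
    for (row in 1:16) {
      g[row, col] <- base * (if (row %in% shade_rows) 0.55 else 1)
    }
  }
  g
}

stim_snake <- function() {
  g <- snake_values(function(group) c(5:8, 13:16))
  g[6:7, 3:4] <- 0.30
  g[10:11, 11:12] <- 0.30
  new_stimulus("snake", g, cells(6:7, 3:4), cells(10:11, 11:12))
}

stim_snake_control <- function() {
  g <- snake_values(function(group) {
    if (group %% 2L == 1L) c(5:8, 13:16) else c(4:7, 12:15)
  })
  g[6:7, 3:4] <- 0.30
  g[10:11, 11:12] <- 0.30
  new_stimulus("snake_control", g, cells(6:7, 3:4), cells(10:11, 11:12))
}

# Classic simultaneous contrast and its articulated variant.
stim_simultaneous_contrast <- function() {
  g <- matrix(0.20, 16, 16)
  g[, 9:16] <- 0.82
  g[7:10, 3:6] <- 0.40
  g[7:10, 11:14] <- 0.40
  new_stimulus("simultaneous_contrast", g, cells(7:10, 3:6), cells(7:10, 11:14))
}

stim_articulated_sc <- function() {
  left_vals <- c(0.07, 0.12, 0.20, 0.30)
  right_vals <- c(0.82, 0.68, 0.56, 0.47)
  g <- matrix(0, 16, 16)
  for (row in 1:16) for (col in 1:16) {
    pair <- (col - 1L) %/% 2L    # 1x2-cell blocks
    idx <- (row + 2L * pair) %% 4L + 1L
    g[row, col] <- if (col <= 8) left_vals[idx] else right_vals[idx]
  }
  g[7:10, 3:6] <- 0.40
  g[7:10, 11:14] <- 0.40
  new_stimulus("articulated_sc", g, cells(7:10, 3:6), cells(7:10, 11:14))
}

# Haze: a translucent veil over part of a checked background. The veil is
# additive as well as multiplicative, so it produces no simple reflectance
# difference between two probe locations and is excluded from scoring.
stim_haze <- function() {
  g <- matrix(0, 16, 16)
  for (row in 1:16) for (col in 1:16) {
    sq <- (row - 1L) %/% 2L + (col - 1L) %/% 2L
    g[row, col] <- if (sq %% 2L == 0L) 0.20 else 0.60
  }
  g[5:12, 5:12] <- 0.5 * g[5:12, 5:12] + 0.35
  new_stimulus("haze", g, expected = "none", scorable = FALSE)
}

STIMULUS_GENERATORS <- list(
  argyle = stim_argyle,
  long_range_argyle = stim_long_range_argyle,
  argyle_control = stim_argyle_control,
  koffka_broken = stim_koffka_broken,
  koffka_adelson = stim_koffka_adelson,
  koffka_connected = stim_koffka_connected,
  whites = stim_whites,
  checkerboard = stim_checkerboard,
  snake = stim_snake,
  snake_control = stim_snake_control,
  simultaneous_contrast = stim_simultaneous_contrast,
  articulated_sc = stim_articulated_sc,
  haze = stim_haze,
  argyle_exp1 = stim_argyle_exp1,
  long_range_argyle_exp1 = stim_long_range_argyle_exp1,
  argyle_control_exp1 = stim_argyle_control_exp1
)

#' List the stimulus catalogue
#'
#' Thirteen grid figures (argyle, long-range argyle, argyle control, broken /
#' Adelson / connected Koffka rings, White's illusion, checkerboard
#' assimilation, snake and snake control, classic and articulated
#' simultaneous contrast, haze) plus the three first-experiment argyle
#' variants whose strip boundaries stop short of the figure edge. The haze
#' figure carries no scorable target pair.
#'
#' @return Character vector of 16 stimulus identifiers, in stable order.
#' @examples
#' mir_stimuli()
#' @export
mir_stimuli <- function() names(STIMULUS_GENERATORS)

#' Construct a catalogued stimulus
#'
#' Builds the named figure as a reflectance grid with its two isoluminant
#' target-cell sets. Coordinates are 1-based `(row, col)` pairs. The green
#' set is the one human observers judge as lighter (for figures with an
#' expected illusion); mirroring reverses columns and remaps the targets
#' consistently.
#'
#' @param name A stimulus identifier from [mir_stimuli()].
#' @param mirrored Return the left-right mirror-reversed version?
#' @return A `mir_stimulus` object: a list with elements `name`,
#'   `reflectance` (matrix of fractions), `targets` (`green`/`red` cell
#'   matrices or `NULL`), `expected` (`"green"` or `"none"`), `scorable`,
#'   `illum_profile` and `mirrored`.
#' @examples
#' s <- mir_stimulus("simultaneous_contrast")
#' dim(s$reflectance)
#' @export
mir_stimulus <- function(name, mirrored = FALSE) {
  gen <- STIMULUS_GENERATORS[[name]]
  if (is.null(gen)) {
    stop(sprintf("unknown stimulus '%s'; see mir_stimuli()", name))
  }
  s <- gen()
  if (mirrored) mirror_stimulus(s) else s
}

#' Mirror a stimulus left-right
#'
#' Columns are reversed and target coordinates remapped; applying it twice
#' restores the original. The green/red identities travel with the cells, so
#' the expected-lighter set lies on the opposite side in the mirrored figure.
#'
#' @param s A `mir_stimulus`.
#' @return The mirrored `mir_stimulus` with the `mirrored` flag toggled.
#' @export
mirror_stimulus <- function(s) {
  stopifnot(inherits(s, "mir_stimulus"))
  W <- ncol(s$reflectance)
  flip <- function(m) if (is.null(m)) NULL else cbind(m[, 1], W + 1L - m[, 2])
  new_stimulus(
    s$name, s$reflectance[, W:1, drop = FALSE],
    green = if (is.null(s$targets)) NULL else flip(s$targets$green),
    red = if (is.null(s$targets)) NULL else flip(s$targets$red),
    expected = s$expected, scorable = s$scorable,
    illum_profile = if (is.null(s$illum_profile)) NULL else
      s$illum_profile[, W:1, drop = FALSE],
    mirrored = !s$mirrored
  )
}

#' Render a reflectance grid to luminance
#'
#' Luminance is the pointwise product of reflectance and illuminance. The
#' default illumination constant is calibrated so paper white (reflectance
#' 0.82) maps to 89 cd/m^2. A stimulus that carries its own illumination
#' profile (e.g. the glow probe) has the profile folded in.
#'
#' @param x A `mir_stimulus` or a reflectance matrix.
#' @param illumination Scalar or matrix of incident light, in units such
#'   that `reflectance * illumination` is cd/m^2. Must be positive.
#' @return Luminance matrix (cd/m^2).
#' @examples
#' mir_render(matrix(0.82, 2, 2))[1, 1]  # 89 cd/m^2
#' @export
mir_render <- function(x, illumination = DEFAULT_ILLUMINANCE) {
  if (inherits(x, "mir_stimulus")) {
    profile <- if (is.null(x$illum_profile)) 1 else x$illum_profile
    x <- x$reflectance * profile
  }
  stopifnot(is.matrix(x), all(x > 0))
  if (any(illumination <= 0)) stop("illumination must be positive everywhere")
  if (is.matrix(illumination) && !all(dim(illumination) == dim(x))) {
    stop("illumination profile does not match the grid")
  }
  x * illumination
}

#' @export
print.mir_stimulus <- function(x, ...) {
  cat(sprintf("Grid stimulus '%s'%s: %d x %d, reflectance %.2f-%.2f\n",
              x$name, if (x$mirrored) " (mirrored)" else "",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$reflectance), max(x$reflectance)))
  if (!is.null(x$targets)) {
    cat(sprintf("  targets: %d green / %d red cells, expected lighter: %s\n",
                nrow(x$targets$green), nrow(x$targets$red), x$expected))
  } else {
    cat("  no scorable targets\n")
  }
  invisible(x)
}

# ---- parametric probe stimuli --------------------------------------------

#' Glow probe stimulus
#'
#' A mid-gray checked field with a centred square luminance outlier of the
#' given width. The outlier is paper white under 1.5x local illumination, so
#' its luminance exceeds what any plausible reflectance could produce under
#' the ambient light; whether the model explains it as glow (reflectance
#' above 1) or by re-estimating the illumination depends on the outlier's
#' size. The field carries gentle two-tone articulation so that the scene,
#' rather than the outlier, anchors the ambient illuminance estimate.
#'
#' @param width Outlier width in cells, between 1 and 14.
#' @return A `mir_stimulus` whose `probe_cells` marks the outlier cells
#'   (not scorable as an illusion).
#' @export
glow_stimulus <- function(width) {
  width <- as.integer(width)
  if (width < 1L || width > 14L) stop("glow outlier width must be in 1..14")
  g <- matrix(0, 16, 16)
  for (row in 1:16) for (col in 1:16) {
    sq <- (row - 1L) %/% 2L + (col - 1L) %/% 2L
    g[row, col] <- if (sq %% 2L == 0L) 0.25 else 0.35
  }
  prof <- matrix(1, 16, 16)
  lo <- (16L - width) %/% 2L + 1L
  idx <- lo:(lo + width - 1L)
  g[idx, idx] <- PAPER_WHITE
  prof[idx, idx] <- 1.5
  s <- new_stimulus("glow", g, expected = "none", scorable = FALSE,
                    illum_profile = prof)
  s$probe_cells <- cells(idx, idx)
  s
}

#' Codetermination probe stimulus
#'
#' The classic simultaneous-contrast geometry with the luminance of the
#' right-hand surround set freely (the two centre patches stay isoluminant).
#'
#' @param right_surround_luminance Luminance of the right surround in
#'   cd/m^2 under the default rendering illumination.
#' @return A `mir_stimulus` carrying an illumination profile over the right
#'   surround.
#' @export
codetermination_stimulus <- function(right_surround_luminance = WHITE_LUMINANCE) {
  if (right_surround_luminance <= 0) stop("surround luminance must be positive")
  s <- stim_simultaneous_contrast()
  prof <- matrix(1, 16, 16)
  right_surround <- matrix(FALSE, 16, 16)
  right_surround[, 9:16] <- TRUE
  right_surround[7:10, 11:14] <- FALSE
  scale <- right_surround_luminance / (PAPER_WHITE * DEFAULT_ILLUMINANCE)
  prof[right_surround] <- scale
  new_stimulus("codetermination", s$reflectance, s$targets$green,
               s$targets$red, expected = s$expected, illum_profile = prof)
}

#' Articulated variant of the simultaneous-contrast figure
#'
#' Subdivides each surround half into `n_subblocks` equal blocks and
#' multiplies each block's luminance by an independent log-normal jitter
#' factor (sigma in natural-log units), leaving the two centre patches
#' untouched. With `jitter_sd = 0` the stimulus equals the base figure.
#'
#' @param n_subblocks Blocks per half; must tile the 16 x 8 half exactly
#'   (1, 4, 16 or 64).
#' @param jitter_sd Standard deviation of the log-normal luminance jitter.
#' @param seed Integer seed; the same seed reproduces the same stimulus.
#' @return A `mir_stimulus`.
#' @export
articulated_variant <- function(n_subblocks = 64L, jitter_sd = 0.3, seed = 1L) {
  n_subblocks <- as.integer(n_subblocks)
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  k <- sqrt(n_subblocks)
  if (k != floor(k) || 16L %% as.integer(k) != 0L || 8L %% as.integer(k) != 0L) {
    stop(sprintf("%d subblocks do not tile a 16 x 8 half", n_subblocks))
  }
  k <- as.integer(k)
  bh <- 16L %/% k; bw <- 8L %/% k
  s <- stim_simultaneous_contrast()
  g <- s$reflectance
  target_mask <- matrix(FALSE, 16, 16)
  target_mask[s$targets$green] <- TRUE
  target_mask[s$targets$red] <- TRUE
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (half in 0:1) for (bi in seq_len(k)) for (bj in seq_len(k)) {
    f <- exp(stats::rnorm(1, 0, jitter_sd))
    rows <- ((bi - 1L) * bh + 1L):(bi * bh)
    colz <- half * 8L + ((bj - 1L) * bw + 1L):(bj * bw)
    block <- matrix(FALSE, 16, 16); block[rows, colz] <- TRUE
    block <- block & !target_mask
    g[block] <- pmin(pmax(g[block] * f, 0.02), 1.0)
  }
  new_stimulus("articulated_variant", g, s$targets$green, s$targets$red,
               expected = s$expected)
}
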