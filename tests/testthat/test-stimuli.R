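test_that("the catalogue lists 16 constructible figures with haze non-scorable", {
  ids <- mir_stimuli()
  expect_length(ids, 16L)
  expect_setequal(
    c("argyle", "long_range_argyle", "argyle_control", "koffka_broken",
      "koffka_adelson", "koffka_connected", "whites", "checkerboard",
      "snake", "snake_control", "simultaneous_contrast", "articulated_sc",
      "haze", "argyle_exp1", "long_range_argyle_exp1", "argyle_control_exp1"),
    ids)
  for (id in ids) {
    s <- mir_stimulus(id)
    expect_s3_class(s, "mir_stimulus")
    expect_true(all(s$reflectance > 0) && all(s$reflectance <= 1.2))
  }
  expect_false(mir_stimulus("haze")$scorable)
  expect_error(mir_stimulus("nonesuch"), "unknown stimulus")
})

test_that("target cell sets are disjoint and exactly isoluminant in every figure", {
  for (id in mir_stimuli()) {
    s <- mir_stimulus(id)
    if (is.null(s$targets)) next
    L <- mir_render(s)
    expect_equal(length(unique(L[s$targets$green])), 1L, info = id)
    expect_identical(unique(L[s$targets$green]), unique(L[s$targets$red]),
                     info = id)
  }
})

test_that("simultaneous contrast has a dark left half, light right half, equal mid-gray patches", {
  s <- mir_stimulus("simultaneous_contrast")
  g <- s$reflectance
  expect_lt(mean(g[, 1:8]), mean(g[, 9:16]))
  expect_identical(unique(g[s$targets$green]), unique(g[s$targets$red]))
  expect_true(all(s$targets$green[, 2] <= 8) && all(s$targets$red[, 2] >= 9))
})

test_that("mirroring is an involution and remaps targets consistently", {
  for (id in c("argyle", "whites", "koffka_broken")) {
    s <- mir_stimulus(id)
    m2 <- mirror_stimulus(mirror_stimulus(s))
    expect_identical(s$reflectance, m2$reflectance, info = id)
    expect_identical(s$targets, m2$targets, info = id)
    m <- mir_stimulus(id, mirrored = TRUE)
    W <- ncol(s$reflectance)
    expect_identical(s$reflectance[, W:1], m$reflectance, info = id)
    expect_setequal(W + 1L - s$targets$green[, 2], m$targets$green[, 2])
  }
})

test_that("rendering is calibrated (0.82 -> 89 cd/m2), linear, and rejects bad input", {
  expect_equal(mir_render(matrix(0.82, 1, 2))[1, 1], 89)
  g <- matrix(c(0.1, 0.4, 0.8, 0.2), 2, 2)
  expect_equal(mir_render(g, 200), g * 200)
  expect_equal(mir_render(g, 100) * 2, mir_render(g, 200))
  expect_error(mir_render(g, -1), "positive")
  expect_error(mir_render(matrix(0, 2, 2)))
  # minimum catalogue reflectance is strictly positive
  expect_true(all(vapply(mir_stimuli(),
    function(id) min(mir_stimulus(id)$reflectance) > 0, logical(1))))
})

test_that("glow and codetermination probe stimuli have the stated geometry", {
  expect_equal(nrow(glow_stimulus(1)$probe_cells), 1L)
  expect_equal(nrow(glow_stimulus(14)$probe_cells), 196L)
  expect_error(glow_stimulus(15), "width")
  # equal left/right surround luminance gives a left-right symmetric stimulus
  s <- codetermination_stimulus(0.20 * 89 / 0.82)
  L <- mir_render(s)
  expect_equal(L, L[, 16:1])
  expect_error(codetermination_stimulus(-5), "positive")
})

test_that("articulated variants are seeded, tile exactly, and leave targets alone", {
  base <- mir_stimulus("simultaneous_contrast")
  expect_equal(articulated_variant(64, jitter_sd = 0, seed = 3)$reflectance,
               base$reflectance)
  a1 <- articulated_variant(64, seed = 11)
  a2 <- articulated_variant(64, seed = 11)
  expect_identical(a1$reflectance, a2$reflectance)
  expect_false(identical(a1$reflectance,
                         articulated_variant(64, seed = 12)$reflectance))
  expect_identical(a1$reflectance[base$targets$green],
                   base$reflectance[base$targets$green])
  expect_error(articulated_variant(9), "tile")
  # 64 subblocks: an 8 x 8 block grid per half
  a <- articulated_variant(64, seed = 2)
  blocks <- unique(as.vector(a$reflectance[1:16, 1:2]))
  expect_gte(length(blocks), 5L)  # 1x2-cell blocks jittered independently
})

test_that("upsampling centres the stimulus in a mean-padded canvas and downsampling inverts it", {
  g <- matrix(runif(16 * 16, 10, 90), 16, 16)
  cv <- mir_upsample(g, factor = 32L, canvas = c(1024L, 1024L))
  expect_equal(dim(cv), c(1024L, 1024L))
  expect_equal(cv[256 + 1, 256 + 1], g[1, 1])
  expect_equal(unique(as.vector(cv[1:256, ])), mean(g))
  expect_equal(mir_downsample(cv), g)
  # long-range argyle: 16 x 24 -> 512 x 768 stimulus region
  lr <- mir_render(mir_stimulus("long_range_argyle"))
  cv2 <- mir_upsample(lr, 32L, canvas = dim(lr) * 32L + 512L)
  expect_equal(dim(cv2), c(1024L, 1280L))
  expect_equal(mir_downsample(cv2), lr)
  expect_error(mir_upsample(g, 32L, canvas = c(256L, 256L)), "canvas")
})
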