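test_that("reflectance cost is zero in the band, monotone and finite outside it", {
  p <- mir_params()
  expect_equal(reflectance_cost(0.5, p), 0)
  expect_equal(reflectance_cost(0.03, p), 0)
  expect_equal(reflectance_cost(0.90, p), 0)
  expect_gt(reflectance_cost(0.95, p), reflectance_cost(0.9, p))
  expect_gt(reflectance_cost(1.1, p), reflectance_cost(0.95, p))
  expect_gt(reflectance_cost(0.01, p), reflectance_cost(0.02, p))
  expect_true(is.finite(reflectance_cost(1.1, p)))   # glow representable
  expect_error(reflectance_cost(0), "positive")
})

test_that("illuminance prior is logarithmic and strictly increasing", {
  p <- mir_params()
  expect_equal(illuminance_prior_cost(1, p), 0)
  e <- c(0.5, 3, 40, 500)
  expect_equal(illuminance_prior_cost(2 * e, p) - illuminance_prior_cost(e, p),
               rep(p$prior_slope * log10(2), length(e)))
  expect_true(all(diff(illuminance_prior_cost(sort(e), p)) > 0))
  expect_error(illuminance_prior_cost(-1, p), "positive")
})

test_that("a 16x16 grid yields 225 finite patch factors over a covering state space", {
  crf <- mir_crf(mir_stimulus("simultaneous_contrast"))
  expect_equal(dim(crf$tables)[4], 225L)
  expect_true(all(is.finite(crf$tables)))
  expect_true(all(is.finite(crf$unary)))
  # every cell can realise the matte band within the level grid
  L <- crf$grid
  r_lo <- min(L) / 10^max(crf$levels)
  r_hi <- max(L) / 10^min(crf$levels)
  expect_lte(r_lo, 0.03)
  expect_gte(r_hi, 1.2)
})

test_that("total energy decomposes exactly into patch potentials", {
  g <- random_grid(5, 5, seed = 21)
  crf <- mir_crf(g, mir_params(n_levels = 6))
  set.seed(22)
  st <- matrix(sample.int(6, 25, replace = TRUE), 5, 5)
  direct <- 0
  for (i in 1:4) for (j in 1:4) {
    direct <- direct + patch_potential(crf, i, j,
      c(st[i, j], st[i, j + 1], st[i + 1, j], st[i + 1, j + 1]))
  }
  expect_equal(crf_energy(crf, st), direct, tolerance = 1e-9)
})

test_that("per-cell terms enter the energy exactly once despite patch overlap", {
  # uniform grid, uniform assignment: no edge or corner terms remain, so the
  # energy must equal the band cost per cell plus one regional prior charge
  g <- matrix(50, 6, 7)
  p <- mir_params(n_levels = 9)
  crf <- mir_crf(g, p)
  for (k in c(1L, 4L, 9L)) {
    lev <- crf$levels[k]
    expected <- sum(reflectance_cost(g / 10^lev, p)) + p$prior_slope * lev
    expect_equal(crf_energy(crf, matrix(k, 6, 7)), expected, tolerance = 1e-9)
  }
})

test_that("with a flat illuminance prior, scaling luminance shifts the MAP but not reflectance", {
  p <- mir_params(prior_slope = 0)
  s <- mir_render(mir_stimulus("simultaneous_contrast"))
  f1 <- mir_decompose(s, p)
  f2 <- mir_decompose(4 * s, p)
  expect_equal(f2$reflectance, f1$reflectance, tolerance = 1e-9)
  expect_equal(log10(f2$illuminance) - log10(f1$illuminance),
               matrix(log10(4), 16, 16), tolerance = 1e-9)
})
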