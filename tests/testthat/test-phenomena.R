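test_that("illusion scoring applies the dead-band and detects empty targets", {
  targets <- list(green = cbind(2, 2), red = cbind(2, 5))
  flat <- matrix(0.5, 6, 6)
  r <- illusion_difference(flat, targets)
  expect_equal(r$difference, 0)
  expect_equal(r$verdict, "none")
  up <- flat; up[2, 2] <- 0.6
  expect_equal(illusion_difference(up, targets)$verdict, "expected")
  dn <- flat; dn[2, 5] <- 0.6
  expect_equal(illusion_difference(dn, targets)$verdict, "reverse")
  expect_error(illusion_difference(flat, list(green = cbind(2, 2)[0, , drop = FALSE],
                                              red = cbind(2, 5))), "empty")
})

test_that("pair strength comparison is symmetric with a tie dead-band", {
  targets <- list(green = cbind(1, 1), red = cbind(1, 3))
  m1 <- matrix(0.4, 2, 3); m1[1, 1] <- 0.8
  m2 <- matrix(0.4, 2, 3); m2[1, 1] <- 0.5
  a <- illusion_difference(m1, targets)
  b <- illusion_difference(m2, targets)
  expect_equal(pair_strength(a, b), "a_stronger")
  expect_equal(pair_strength(b, a), "b_stronger")
  expect_equal(pair_strength(a, a), "tie")
})

test_that("verdicts are preserved under mirror reversal of the stimulus", {
  for (nm in c("simultaneous_contrast", "argyle")) {
    v1 <- illusion_difference(cached_fit(nm))
    v2 <- illusion_difference(cached_fit(nm, mirrored = TRUE))
    expect_equal(v1$verdict, v2$verdict, info = nm)
    expect_equal(v1$difference, v2$difference, tolerance = 1e-9, info = nm)
  }
})

test_that("highest-luminance statistics segment the fitted illuminance map", {
  fit <- cached_fit("whites")        # uniform illuminance interpretation
  hl <- highest_luminance_stats(fit)
  expect_equal(nrow(hl), 1L)
  expect_true(hl$strong[1])
  expect_gt(hl$max_reflectance[1], 0.8)
  fa <- cached_fit("argyle")         # four lighting strips
  ha <- highest_luminance_stats(fa)
  expect_equal(nrow(ha), 4L)
  expect_true(all(ha$strong))
  expect_true(all(ha$max_reflectance >= 0.8))
})

test_that("the articulation probe is seeded and reproducible", {
  c1 <- articulation_curve(c(1, 64), n_samples = 1, seed = 3, model = "mir")
  c2 <- articulation_curve(c(1, 64), n_samples = 1, seed = 3, model = "mir")
  expect_identical(c1, c2)
  expect_gt(c1$effect[2], c1$effect[1])
})
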