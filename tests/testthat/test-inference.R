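test_that("belief propagation matches the exhaustive oracle on random small instances", {
  for (k in 1:8) {
    crf <- mir_crf(random_grid(3, 3, seed = 100 + k), mir_params(n_levels = 4))
    ex <- exhaustive_map(crf)
    bp <- max_sum_bp(crf)
    expect_equal(bp$energy, ex$energy, tolerance = 1e-9, info = paste("seed", k))
  }
})

test_that("the oracle refuses oversized instances and beats random assignments", {
  crf <- mir_crf(random_grid(3, 3, seed = 7), mir_params(n_levels = 4))
  ex <- exhaustive_map(crf)
  set.seed(8)
  for (r in 1:50) {
    st <- matrix(sample.int(4, 9, replace = TRUE), 3, 3)
    expect_gte(crf_energy(crf, st), ex$energy - 1e-12)
  }
  big <- mir_crf(random_grid(5, 5, seed = 9), mir_params(n_levels = 10))
  expect_error(exhaustive_map(big), "too large")
})

test_that("decoding is exact on tree-structured (two-patch) graphs without polish", {
  for (k in 1:5) {
    crf <- mir_crf(random_grid(2, 3, seed = 200 + k), mir_params(n_levels = 5))
    bp <- max_sum_bp(crf, polish = FALSE, max_iter = 100)
    ex <- exhaustive_map(crf)
    expect_equal(bp$energy, ex$energy, tolerance = 1e-9)
    expect_true(bp$converged)
  }
})

test_that("inference is deterministic and reports non-convergence gracefully", {
  s <- mir_stimulus("simultaneous_contrast")
  f1 <- mir_decompose(s)
  f2 <- mir_decompose(s)
  expect_identical(f1$states, f2$states)
  expect_identical(f1$energy, f2$energy)
  crf <- mir_crf(random_grid(3, 3, seed = 4), mir_params(n_levels = 4))
  f3 <- max_sum_bp(crf, max_iter = 1, polish = FALSE)
  expect_s3_class(f3, "mir_fit")
  expect_false(f3$converged)
})

test_that("decompositions reproduce the input luminance exactly", {
  for (nm in c("simultaneous_contrast", "argyle", "whites")) {
    fit <- cached_fit(nm)
    expect_equal(fitted(fit), fit$luminance, tolerance = 1e-12, info = nm)
    expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12, info = nm)
  }
})

test_that("the decoded 16x16 state is a single-cell local optimum", {
  fit <- cached_fit("simultaneous_contrast")
  crf <- mir_crf(fit$luminance, fit$params)
  pol <- mirlight:::mir_icm_cpp(crf$tables, crf$unary,
                                as.integer(fit$states) - 1L, crf$H, crf$W,
                                length(crf$levels), crf$w_corner, 1L)
  expect_identical(pol$states + 1L, as.integer(fit$states))
})

test_that("the argyle is decomposed into lighting strips, its control into uniform lighting", {
  fa <- cached_fit("argyle")
  ill <- log10(fa$illuminance)
  expect_gt(mean(ill[, c(1:4, 9:12)]) - mean(ill[, c(5:8, 13:16)]), 0.2)
  expect_equal(illusion_difference(fa)$verdict, "expected")
  fc <- cached_fit("argyle_control")
  expect_equal(illusion_difference(fc)$verdict, "none")
})
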