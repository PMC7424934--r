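canvas_for <- function(name) {
  g <- mir_render(mir_stimulus(name))
  mir_upsample(g, 32L, canvas = dim(g) * 32L + 512L)
}

test_that("the high-pass model is linear, removes DC, and degenerates at width 1", {
  cv <- canvas_for("simultaneous_contrast")
  r1 <- highpass(cv)
  r2 <- highpass(mir_upsample(2 * mir_render(mir_stimulus("simultaneous_contrast")),
                              32L, canvas = c(1024L, 1024L)))
  expect_equal(unclass(r2)[1:50, 1:50], 2 * unclass(r1)[1:50, 1:50],
               tolerance = 1e-9)
  expect_lt(abs(mean(r1)), 1e-6 * diff(range(cv)))
  expect_equal(max(abs(highpass(cv, 1L))), 0)
  expect_error(highpass(cv, 5000L), "wider")
})

test_that("oriented DoG responses vanish on uniform input and normalise contrast", {
  cv <- mir_upsample(matrix(40, 16, 16), 16L, canvas = c(512L, 512L))
  expect_lt(diff(range(odog(cv))), 1e-6)
  # doubling contrast about the mean leaves RMS-normalised output unchanged
  g <- mir_render(mir_stimulus("whites"))
  c1 <- mir_upsample(g, 16L, canvas = c(512L, 512L))
  c2 <- mir_upsample(mean(g) + 2 * (g - mean(g)), 16L, canvas = c(512L, 512L))
  o1 <- odog(c1); o2 <- odog(c2)
  expect_equal(unclass(o2)[200:300, 200:300], unclass(o1)[200:300, 200:300],
               tolerance = 1e-6)
})

test_that("retinex output is bounded by the scene maximum and uniform on uniform input", {
  cv <- canvas_for("simultaneous_contrast")
  r <- retinex_mccann(cv)
  expect_lte(max(r), 1 + 1e-12)
  expect_gt(min(r), 0)
  flat <- mir_upsample(matrix(25, 16, 16), 16L, canvas = c(512L, 512L))
  expect_equal(diff(range(retinex_mccann(flat))), 0)
  expect_error(retinex_mccann(cv - 2 * min(cv)), "positive")
})

test_that("block-mean downsampling averages the stimulus region only", {
  g <- matrix(rep(c(10, 20), each = 8), 16, 16)
  cv <- mir_upsample(g, 32L, canvas = c(1024L, 1024L))
  expect_equal(mir_downsample(cv), g)
  # a constant response downsample stays constant regardless of padding
  resp <- mirlight:::as_response(matrix(3.5, 1024, 1024), cv, "test")
  expect_equal(mir_downsample(resp), matrix(3.5, 16, 16))
})

test_that("all three comparison models predict classic simultaneous contrast", {
  for (m in c("odog", "highpass", "retinex")) {
    expect_equal(illusion_difference(cached_response(m, "simultaneous_contrast"))$verdict,
                 "expected", info = m)
  }
})
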