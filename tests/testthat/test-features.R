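test_that("uniform region segmentation uses 4-connectivity on equal luminance", {
  expect_equal(segment_regions(matrix(5, 4, 4))$n_regions, 1L)
  # classic simultaneous contrast: two surrounds + two centre patches
  seg <- segment_regions(mir_render(mir_stimulus("simultaneous_contrast")))
  expect_equal(seg$n_regions, 4L)
  # diagonal-touching equal squares are separate components
  g <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_equal(segment_regions(g)$n_regions, 4L)
})

test_that("luminance edge detection flags exactly the piecewise-constant boundaries", {
  expect_equal(detect_edges(matrix(7, 3, 3))$n_edges, 0L)
  half <- cbind(matrix(10, 4, 2), matrix(40, 4, 2))
  ed <- detect_edges(half)
  expect_equal(ed$n_edges, 4L)
  expect_true(all(ed$h_edge[, 2]))
  # edge count on the simultaneous-contrast grid equals the boundary length
  # of its 4 regions: 16 midline edges + 2 target perimeters of 16
  ed2 <- detect_edges(mir_render(mir_stimulus("simultaneous_contrast")))
  expect_equal(ed2$n_edges, 16L + 16L + 16L)
})

test_that("X-junction detection follows the ratio identity and ignores plain edges", {
  pj <- function(v) detect_xjunctions(matrix(v, 2, 2, byrow = TRUE))
  hit <- pj(c(10, 20, 30, 60))          # 10*60 == 20*30
  expect_equal(hit$score[1, 1], 1)
  expect_equal(hit$orientation[1, 1], "vertical")
  expect_equal(pj(c(10, 20, 30, 40))$score[1, 1], 0)
  expect_equal(pj(c(10, 10, 10, 10))$score[1, 1], 0)
  # a straight uniform boundary (two equal rows) is not a junction
  expect_equal(pj(c(10, 40, 10, 40))$score[1, 1], 0)
  # invariant to global luminance scaling (ratios only)
  g <- matrix(c(12, 33, 21, 57.75), 2, 2)
  expect_equal(detect_xjunctions(g)$score, detect_xjunctions(7.3 * g)$score)
})
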