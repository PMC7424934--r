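test_that("the single-stimulus set has 24 members and the paired set 14", {
  sets <- make_experiment_sets()
  expect_length(sets$single, 24L)
  expect_equal(nrow(sets$pairs), 14L)
  expect_equal(sum(vapply(sets$single, function(s) s$mirrored, logical(1))), 12L)
  # each pair appears once per placement
  expect_equal(unname(table(sets$pairs$pair_id)), rep(2L, 7L), ignore_attr = TRUE)
  # every mirrored member equals the mirror of its base
  base <- sets$single[[1]]; mirr <- sets$single[[2]]
  expect_identical(mirror_stimulus(base)$reflectance, mirr$reflectance)
})

test_that("expected sides flip with mirroring", {
  expect_equal(expected_side("simultaneous_contrast"), "left")
  expect_equal(expected_side("simultaneous_contrast", mirrored = TRUE), "right")
  expect_true(is.na(expected_side("haze")))
})

test_that("'same' responses earn half credit in the expected proportion", {
  tt <- data.frame(
    observer = rep(1:20, 2),
    condition = rep(c("all_expected", "half_same"), each = 20),
    placement = "left",
    response = c(rep("left", 20), rep(c("left", "same"), each = 10))
  )
  sc <- score_expected_proportion(tt)
  sc <- sc[order(sc$condition), ]
  expect_equal(sc$proportion[sc$condition == "all_expected"], 1.0)
  expect_equal(sc$expected_count[sc$condition == "half_same"], 15)
  expect_equal(sc$proportion[sc$condition == "half_same"], 0.75)
  # chance-level data: the confidence interval covers 0.5
  tc <- data.frame(observer = 1:20, condition = "chance", placement = "left",
                   response = rep(c("left", "right"), 10))
  s2 <- score_expected_proportion(tc)
  expect_lte(s2$ci_low, 0.5)
  expect_gte(s2$ci_high, 0.5)
  expect_error(score_expected_proportion(tt, c(all_expected = "left")),
               "missing")
})

test_that("synthetic trials are seeded binomials that recover their proportions", {
  p <- c(easy = 1.0, mid = 0.5)
  t1 <- synth_trials(p, n_observers = 50, seed = 9)
  t2 <- synth_trials(p, n_observers = 50, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$response[t1$condition == "easy"] == "left"))
  sc <- score_expected_proportion(t1)
  mid <- sc[sc$condition == "mid", ]
  expect_lte(mid$ci_low, 0.5)
  expect_gte(mid$ci_high, 0.5)
  expect_error(synth_trials(c(a = 1.5)), "0, 1")
})

test_that("Wilson intervals have near-nominal coverage on seeded binomial data", {
  set.seed(42)
  n <- 20L
  covered <- logical(1000)
  for (k in seq_len(1000)) {
    p <- runif(1, 0.15, 0.85)
    x <- rbinom(1, n, p)
    ci <- wilson_ci(x, n)
    covered[k] <- ci[1] <= p && p <= ci[2]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("trial tables round-trip through CSV", {
  tt <- synth_trials(c(a = 0.8, b = 0.3), n_observers = 5, seed = 2,
                     same_rate = 0.2)
  path <- tempfile(fileext = ".csv")
  write_trials(tt, path)
  expect_equal(read_trials(path), tt, ignore_attr = TRUE)
  expect_error(read_trials(write_grid(matrix(1, 2, 2), tempfile())))
})
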