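test_that("pure tones are located within one grid bin across sampling rates", {
  for (fs in c(200, 1000, 10000)) {
    t <- seq(0, 10, by = 1 / fs)
    sp <- welch_psd(sin(2 * pi * 20 * t), fs)
    expect_lt(abs(sp$dominant_frequency - 20), sp$df + 1e-12)
  }
})

test_that("the larger-amplitude tone dominates a two-tone mixture", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  x <- 2 * sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t)
  sp <- welch_psd(x, fs)
  expect_lt(abs(sp$dominant_frequency - 10), sp$df + 1e-12)
})

test_that("constant signals give a flat near-zero spectrum", {
  sp <- welch_psd(rep(3.7, 2048), 1000)
  expect_lt(max(sp$power), 1e-20)
})

test_that("welch estimate approximates the signal variance (Parseval)", {
  set.seed(1)
  x <- stats::rnorm(8192)
  sp <- welch_psd(x, 1000)
  expect_equal(sum(sp$power) * sp$df, stats::var(x), tolerance = 0.25)
})

test_that("band power is additive over adjacent half-open bands", {
  t <- seq(0, 10, by = 1e-3)
  sp <- welch_psd(sin(2 * pi * 20 * t), 1000)
  expect_equal(band_power(sp, c(13, 20)) + band_power(sp, c(20, 30)),
               band_power(sp, c(13, 30)))
  # a 20 Hz tone carries essentially all its power in the beta band
  expect_gt(band_power(sp, c(13, 30)) / (sum(sp$power) * sp$df), 0.95)
  sp50 <- welch_psd(sin(2 * pi * 50 * t), 1000)
  expect_lt(band_power(sp50, c(13, 30)) / (sum(sp50$power) * sp50$df), 0.01)
  expect_error(band_power(sp, c(30, 13)), "inverted")
})

test_that("signals too short for two segments are rejected", {
  expect_error(welch_psd(stats::rnorm(20), 1000, segment = 64), "too short")
})

test_that("oscillation classes: steady, damped, and silent signals", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  steady <- oscillation_class(sin(2 * pi * 15 * t), fs)
  expect_equal(steady$class, "sustained")
  expect_lt(abs(steady$frequency - 15), 0.5)
  damped <- oscillation_class(exp(-t / 0.29) * sin(2 * pi * 15 * t), fs)
  expect_equal(damped$class, "transient")
  set.seed(2)
  quiet <- oscillation_class(1e-5 * stats::rnorm(length(t)), fs)
  expect_equal(quiet$class, "none")
})

test_that("classification is invariant to amplitude rescaling above the floor", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * 18 * t)
  for (scale in c(0.01, 1, 100))
    expect_equal(oscillation_class(scale * x, fs)$class, "sustained")
})

test_that("trajectory classification covers the constructed cases", {
  expect_equal(classify_trajectory(matrix(1, 200, 2)), "converged-fixed-point")
  tt <- seq(0, 100, by = 0.01)
  expect_equal(classify_trajectory(cbind(sin(tt), cos(tt))),
               "sustained-oscillation")
  # damped at rate 0.1 per time unit: oscillatory early, below floor late
  tt2 <- seq(0, 120, by = 0.01)
  expect_equal(classify_trajectory(cbind(exp(-0.1 * tt2) * sin(2 * tt2))),
               "transient-oscillation")
  expect_error(classify_trajectory(matrix(1, 4, 1)), "too short")
})
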