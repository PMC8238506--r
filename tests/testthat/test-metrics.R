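test_that("three-point Hanning smoothing preserves constants and contracts variation", {
  expect_identical(hanning3_smooth(rep(2.5, 7)), rep(2.5, 7))
  expect_equal(hanning3_smooth(c(0, 4, 0))[2], 2)
  expect_error(hanning3_smooth(c(1, 2)), "too short")
  set.seed(3)
  x <- rpois(30, 2)
  tv <- function(v) sum(abs(diff(v)))
  expect_lte(tv(hanning3_smooth(x)), tv(x))
})

test_that("halfwidth of a V-shaped curve is the analytic crossing width", {
  itd <- seq(-2, 2, by = 0.1)
  v <- pmin(1, abs(itd))           # trough at 0, flanks of slope 1/ms
  expect_equal(halfwidth(itd, v, "trough"), 1)
  # invariant to uniform scaling and axis translation
  expect_equal(halfwidth(itd, 3.7 * v, "trough"), 1)
  expect_equal(halfwidth(itd + 0.8, v, "trough"), 1)
  # peaked version
  expect_equal(halfwidth(itd, 1 - v, "peak"), 1)
  # flat curve and never-crossing curves are undefined
  expect_true(is.na(halfwidth(itd, rep(1, length(itd)), "trough")))
  expect_true(is.na(halfwidth(itd, 0.8 + 0.2 * v, "trough")))
})

test_that("20-80% slopes carry sign and undefined sides", {
  itd <- seq(-2, 2, by = 0.1)
  v <- pmin(1, abs(itd))
  s <- slopes_20_80(itd, v, "trough")
  expect_equal(unname(s["left"]), -1, tolerance = 1e-9)
  expect_equal(unname(s["right"]), 1, tolerance = 1e-9)
  # uniform scaling scales the slopes, not the crossing geometry
  s2 <- slopes_20_80(itd, 2 * v, "trough")
  expect_equal(unname(s2), 2 * unname(s), tolerance = 1e-9)
  # monotone curve: only one side defined
  mono <- pmin(1, pmax(0, itd + 1))
  sm <- slopes_20_80(itd, mono, "trough")
  expect_true(is.na(sm["left"]))
  expect_false(is.na(sm["right"]))
})

test_that("ITD-SNR reproduces hand computations and limits", {
  expect_equal(itd_snr(rbind(c(1, 1), c(0, 1)), min_reps = 2), 1 / 3)
  expect_identical(itd_snr(rbind(c(2, 2), c(2, 2)), min_reps = 2), 0)
  expect_equal(itd_snr(rbind(c(1, 1), c(0, 0), c(3, 3)), min_reps = 2), 1)
  # data-frame interface, inclusion rule, ragged handling
  df <- data.frame(condition_value = rep(c(-1, 1), each = 2),
                   spike_count = c(1, 1, 0, 1))
  expect_equal(itd_snr(df, min_reps = 2), 1 / 3)
  expect_error(itd_snr(df), "repetitions")
  ragged <- data.frame(condition_value = c(-1, -1, 1, 1, 1),
                       spike_count = c(1, 1, 0, 1, 1))
  expect_error(itd_snr(ragged, min_reps = 2), "ragged")
  expect_true(itd_snr(ragged, min_reps = 2, allow_ragged = TRUE) <= 1)
})

test_that("summation ratios match hand examples in both modes", {
  rl0 <- data.frame(spl = c(30, 40), ipsi = c(0.6, 0.8), contra = c(0.2, 0.1),
                    bin = c(0.8, 0.9))
  expect_equal(summation_ratio(rl0, "LSO"), 1)
  expect_equal(summation_ratio(rl0, "MSO"), 1)
  rl <- data.frame(spl = c(40, 50), ipsi = c(1, 1), contra = c(0, 0),
                   bin = c(0.5, 0.25))
  expect_equal(summation_ratio(rl, "LSO"), 3)
  # MSO facilitation >> 1
  rlm <- data.frame(spl = 30:32, ipsi = 0.1, contra = 0.1, bin = c(1, 1.5, 2))
  expect_gt(summation_ratio(rlm, "MSO"), 5)
  # zero denominators are excluded; all-zero errors out
  rlz <- data.frame(spl = c(30, 40), ipsi = c(1, 1), contra = 0, bin = c(0, 0.5))
  expect_message(v <- summation_ratio(rlz, "LSO"), "excluded")
  expect_equal(v, 2)
  rlz$bin <- 0
  expect_error(summation_ratio(rlz, "LSO"), "no valid levels")
})

test_that("PSP latency is the interpolated fractional-amplitude crossing", {
  t <- seq(0, 10, by = 0.05)
  # linear ramp 1 mV/ms from t0 = 2: 20% of 5 mV crossed 1 ms after onset
  ramp <- -60 + pmax(0, t - 2)
  expect_equal(psp_latency(t, ramp, -60, 5, "depolarizing", t0 = 2), 1,
               tolerance = 1e-9)
  # hyperpolarizing double exponential: crossing equals the kernel root
  k <- kernel_peak(0.45, 2)
  shape <- function(x) (exp(-x / 2) - exp(-x / 0.45)) / k$norm
  v <- -60 - 5 * ifelse(t < 1, 0, shape(t - 1))
  t20 <- uniroot(function(x) shape(x) - 0.2, c(1e-9, k$t_peak), tol = 1e-12)$root
  expect_equal(psp_latency(t, v, -60, 5, "hyperpolarizing", t0 = 0),
               1 + t20, tolerance = 0.01)
  # flat trace undefined; wrong polarity undefined
  expect_true(is.na(psp_latency(t, rep(-60, length(t)), -60, 5, "depolarizing")))
  expect_true(is.na(psp_latency(t, ramp, -60, 5, "hyperpolarizing", t0 = 2)))
})

test_that("theta effect size handles separation, ties, and complementarity", {
  expect_identical(theta_effect_size(c(3, 4), c(1, 2)), 1)
  expect_identical(theta_effect_size(c(1, 2), c(1, 2)), 0.5)
  expect_identical(theta_effect_size(c(1, 4), c(2, 3)), 0.5)
  expect_error(theta_effect_size(numeric(0), 1), "empty")
  set.seed(8)
  x <- rnorm(13); y <- rnorm(9)
  # complementarity for tie-free samples
  expect_equal(theta_effect_size(x, y) + theta_effect_size(y, x), 1)
  # agrees with the rank-sum statistic
  w <- unname(wilcox.test(x, y)$statistic)
  expect_equal(theta_effect_size(x, y), w / (13 * 9))
})

test_that("cue-map coordinates scale ITD and assign nearest sites", {
  map <- cue_map(itd = c(0.05, -0.1, 0.2), iid = c(0, 5, -5))
  expect_equal(map$x, c(1, -2, 4))
  expect_equal(map$y, c(0, 5, -5))
  # brute-force nearest-site oracle over random queries
  set.seed(4)
  qi <- runif(20, -0.3, 0.3); qd <- runif(20, -8, 8)
  got <- cue_region(map, qi, qd)
  for (j in seq_along(qi)) {
    d2 <- (map$x - qi[j] / 0.05)^2 + (map$y - qd[j])^2
    expect_identical(got[j], which(d2 == min(d2))[1])
  }
  # equidistant query breaks ties to the lower site index
  tie_map <- cue_map(itd = c(-0.05, 0.05, 0), iid = c(0, 0, 10))
  expect_identical(cue_region(tie_map, 0, 0), 1L)
  expect_error(cue_map(itd = 0.1, iid = 1), "degenerate")
  expect_message(cue_map(itd = c(0, 0.05, 0.1), iid = c(0, 0, 0)), "collinear")
})

test_that("per-cell averaging collapses datasets before population statistics", {
  expect_identical(unname(cell_average(c(0.4, 0.9), c("a", "b"))), c(0.4, 0.9))
  expect_equal(unname(cell_average(c(0.5, 0.7), c("a", "a"))), 0.6)
  expect_error(cell_average(1:3, c("a", NA, "b")), "missing cell id")
  # pooled vs per-cell medians genuinely differ on an unbalanced design
  vals <- c(0.1, 0.9, 0.9, 0.9)
  cells <- c("c1", "c2", "c2", "c2")
  expect_equal(median(cell_average(vals, cells)), 0.5)
  expect_equal(median(vals), 0.9)
})
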