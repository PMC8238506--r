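test_that("generators are bit-reproducible under a fixed seed", {
  sp <- synth_spec(seed = 123)
  expect_identical(gen_trial_table(sp), gen_trial_table(sp))
  a <- gen_psp_trace(sp, "contra", spl = 50)
  b <- gen_psp_trace(sp, "contra", spl = 50)
  expect_identical(a$V, b$V)
  # a different seed gives different draws
  sp2 <- synth_spec(seed = 124)
  expect_false(identical(gen_trial_table(sp)$spike_count,
                         gen_trial_table(sp2)$spike_count))
})

test_that("principal-LSO tables are Bernoulli, other classes can exceed one spike", {
  tt <- gen_trial_table(synth_spec(seed = 5))
  expect_true(all(tt$spike_count %in% c(0L, 1L)))
  mso <- gen_trial_table(synth_spec(cell_class = "MSO", floor = 0.2,
                                    ceiling = 2.5, seed = 5))
  expect_gt(max(mso$spike_count), 1)
})

test_that("profile ground truth matches the spec parameters", {
  sp <- synth_spec(center = 0.2, halfwidth = 0.8, floor = 0, ceiling = 1,
                   seed = 1)
  tr <- profile_truth(sp)
  expect_equal(tr$halfwidth, 0.8, tolerance = 0.01)
  expect_lt(tr$slopes["left"], 0)
  expect_gt(tr$slopes["right"], 0)
  # flat profile: no halfwidth, zero generative ITD-SNR
  fl <- synth_spec(floor = 0.5, ceiling = 0.5, seed = 1)
  trf <- profile_truth(fl)
  expect_true(is.na(trf$halfwidth))
  expect_equal(trf$itd_snr, 0)
})

test_that("metrics recover the generative halfwidth and ITD-SNR", {
  sp <- synth_spec(halfwidth = 0.8, n_reps = 500, seed = 7)
  tt <- gen_trial_table(sp)
  truth <- attr(tt, "truth")
  agg <- aggregate(spike_count ~ condition_value, tt, mean)
  hw <- tuning_metrics(agg$condition_value, agg$spike_count, "trough")$halfwidth
  step <- diff(sp$itd_grid)[1]
  expect_lt(abs(hw - truth$halfwidth), step)
  snr <- itd_snr(tt)
  p <- tuning_profile(sp)(sp$itd_grid)
  se <- sd(replicate(200, {            # quick parametric bootstrap SE
    counts <- matrix(rbinom(length(p) * 50, 1, rep(p, each = 50)),
                     nrow = length(p), byrow = TRUE)
    itd_snr(counts, min_reps = 50)
  }))
  expect_lt(abs(snr - truth$itd_snr), 3 * se + 0.02)
})

test_that("a flat profile yields near-zero measured ITD-SNR", {
  sp <- synth_spec(floor = 0.5, ceiling = 0.5, n_reps = 200, seed = 11)
  tt <- gen_trial_table(sp)
  expect_lt(itd_snr(tt), 0.1)
})

test_that("rate-level construction hits the target summation ratio exactly", {
  sp <- synth_spec(seed = 1)
  expect_equal(summation_ratio(gen_rate_level(sp, "MSO", 1), "MSO"), 1)
  expect_equal(summation_ratio(gen_rate_level(sp, "LSO", 3), "LSO"), 3)
  # the median is robust to one outlier level
  rl <- gen_rate_level(sp, "LSO", 2, spl = c(30, 40, 50),
                       spread = c(0.1, 1, 10))
  expect_equal(summation_ratio(rl, "LSO"), 2)
})

test_that("noise-free PSP traces return the analytic latency", {
  sp <- synth_spec(noise_sd = 0, seed = 1)
  for (ear in c("ipsi", "contra")) {
    trc <- gen_psp_trace(sp, ear, spl = 50)
    pol <- attr(trc, "polarity")
    lat <- psp_latency(trc$t, trc$V, -60, sp$psp_amp, pol)
    expect_lt(abs(lat - attr(trc, "latency_truth")), 0.01)
  }
  # hyperpolarizing trace stays at or below rest (up to noise = 0 here)
  trc <- gen_psp_trace(sp, "contra", spl = 50)
  expect_lte(max(trc$V), -60 + 1e-9)
  expect_lt(min(trc$V), -60 - 3)
})

test_that("latency-level slope is recovered from noisy traces", {
  sp <- synth_spec(noise_sd = 0.2, latency_slope = 15, seed = 3)
  spls <- seq(35, 65, by = 5)
  lat <- vapply(spls, function(s) {
    trc <- gen_psp_trace(sp, "contra", spl = s)
    psp_latency(trc$t, trc$V, -60, sp$psp_amp, "hyperpolarizing")
  }, numeric(1))
  slope_us_db <- -1000 * unname(coef(lm(lat ~ spls))[2])
  expect_lt(abs(slope_us_db - 15), 1)
})
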