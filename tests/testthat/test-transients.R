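test_that("extract_trace averages roi pixels; single-pixel roi is an identity", {
  fr <- array(stats::rnorm(10 * 3 * 3, 100, 5), dim = c(10, 3, 3))
  stk <- frame_stack(abs(fr), 110, 10)
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 1L; lab[1, ] <- 2L
  rois <- roi_set(lab)
  tr1 <- extract_trace(stk, rois, 1)
  expect_equal(tr1$samples, stk$frames[, 2, 2])
  tr2 <- extract_trace(stk, rois, 2)
  expect_equal(tr2$samples, apply(stk$frames[, 1, , drop = FALSE], 1, mean))
  expect_equal(tr1$sample_interval, 110)
  # constant stack gives a constant trace
  cst <- frame_stack(array(100, dim = c(5, 2, 2)), 110, 10)
  expect_true(all(extract_trace(cst, matrix(TRUE, 2, 2))$samples == 100))
  expect_error(extract_trace(stk, rois, 99), "no pixels")
})

test_that("noiseless periodic transients yield exact intervals and counts", {
  g <- gen_spontaneous_traces(n_cells = 1, period_sd = 0, tau_sd = 0,
                              noise_sd = 0, seed = 9)
  df <- g$traces
  tr <- fluor_trace(df$value, 20, "cell_001")
  m <- detect_transients(tr)
  expect_equal(length(m$peak_times), length(g$truth[[1]]$onsets))
  expect_true(all(abs(m$intervals - 1000) <= 20))
  # flat trace: zero peaks, empty metrics rather than an error
  flat <- fluor_trace(rep(100, 50), 20)
  expect_length(detect_transients(flat)$peak_times, 0)
})

test_that("CaT50 equals tau log 2 on noiseless exponential decays", {
  for (tau in c(200, 300, 408, 500)) {
    tr <- exp_decay_trace(tau)
    m <- detect_transients(tr)
    v <- cat50(tr, m$peak_times[1])
    expect_lt(abs(v - tau * log(2)), 10)   # half the 20 ms sample interval
  }
  # tau = 408 reproduces the 283 ms scenario
  tr <- exp_decay_trace(408)
  expect_equal(cat50(tr, detect_transients(tr)$peak_times[1]),
               283, tolerance = 0.01)
})

test_that("CaT50 handles degenerate and unmeasurable decays", {
  # instantaneous drop one sample after the peak
  v <- c(rep(100, 10), 200, rep(100, 10))
  tr <- fluor_trace(v, 20)
  d <- cat50(tr, 10 * 20, baseline = 100)
  expect_lte(d, 20)
  # never decays below 50 %: flagged unmeasurable, not an error
  v2 <- c(rep(100, 10), rep(200, 30))
  u <- cat50(fluor_trace(v2, 20), 10 * 20, baseline = 100)
  expect_true(is.na(u))
  expect_true(attr(u, "unmeasurable"))
})

test_that("FWHM convention exceeds peak-to-half-decay on an asymmetric transient", {
  tr <- exp_decay_trace(400)
  pk <- detect_transients(tr)$peak_times[1]
  a <- cat50(tr, pk, baseline = 100)
  b <- cat50(tr, pk, method = "fwhm", baseline = 100)
  expect_gte(b, a)          # instantaneous rise: upstroke adds < 1 sample
  expect_lt(b - a, 21)
})

test_that("diastolic asymptote estimation removes the residual-floor bias", {
  # at 1 Hz firing with tau = 408 ms the trace floor sits ~9 % of the
  # amplitude above diastole; the asymptote estimator must see through it
  g <- gen_spontaneous_traces(n_cells = 1, period_sd = 0, tau_sd = 0,
                              noise_sd = 0.5, seed = 21)
  df <- g$traces
  tr <- fluor_trace(df$value, 20, "c1")
  m <- detect_transients(tr)
  b <- estimate_diastolic(tr, m$peak_frames)
  expect_lt(abs(b - 100), 2)
  # once firing is underway the raw floor really is elevated (the only
  # true-baseline samples precede the first onset)
  expect_gt(min(tr$samples[df$time_ms > 2000]) - 100, 4)
})

test_that("regularity classification matches the printed bins and ignores order", {
  expect_equal(classify_regularity(c(990, 1010, 1005)), "regular")
  expect_equal(classify_regularity(c(6000, 7000)), "irregular")
  expect_equal(classify_regularity(2000), "intermediate")
  iv <- c(990, 1010, 1005, 940, 1080)
  for (i in 1:5)
    expect_equal(classify_regularity(sample(iv)),
                 classify_regularity(iv))
})

test_that("summarize_cat50 filters by class and demands two values", {
  tab <- tibble::tibble(
    id = letters[1:5],
    cat50_ms = c(283, 283, 283, 400, NA),
    class = c("regular", "regular", "regular", "intermediate", "regular"))
  s <- summarize_cat50(tab, "regular")
  expect_equal(s$mean_ms, 283)
  expect_equal(s$sd_ms, 0)
  expect_equal(s$n, 3)
  expect_error(summarize_cat50(tab, "irregular"), "irregular")
})
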