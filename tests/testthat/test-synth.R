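test_that("generators are reproducible: identical seeds give identical output", {
  a <- gen_wave_movie(grid = c(4, 12), pixel_size = 10, cv = 20,
                      frame_interval = 110, seed = 11)
  b <- gen_wave_movie(grid = c(4, 12), pixel_size = 10, cv = 20,
                      frame_interval = 110, seed = 11)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$start_phase, b$truth$start_phase)

  ta <- gen_spontaneous_traces(n_cells = 3, seed = 5)
  tb <- gen_spontaneous_traces(n_cells = 3, seed = 5)
  expect_identical(ta$traces, tb$traces)

  ia <- gen_cell_image(cell_image_truth(60, 20), seed = 2)
  ib <- gen_cell_image(cell_image_truth(60, 20), seed = 2)
  expect_identical(ia$image, ib$image)

  sa <- gen_ephys_sweeps(ephys_truth(), seed = 3)
  sb <- gen_ephys_sweeps(ephys_truth(), seed = 3)
  expect_identical(sa$sweeps, sb$sweeps)
})

test_that("wave-movie truth geometry: traversal time is length over velocity", {
  # 300 um strip at 20.55 mm/s -> T = 14.6 ms
  sim <- gen_wave_movie(grid = c(2, 31), pixel_size = 10, cv = 20.55,
                        frame_interval = 110, seed = 1)
  expect_equal(sim$truth$t_traverse, 300 / 20.55, tolerance = 1e-10)
  # near-infinite velocity: a simultaneous flash, all onsets equal
  fl <- gen_wave_movie(grid = c(3, 10), pixel_size = 10, cv = 1e9,
                       frame_interval = 110, seed = 2)
  act <- fl$truth$activation_true
  expect_lt(diff(range(act)), 1e-3)
  # cluster length from the mask caliper
  expect_equal(sim$truth$cluster_length,
               mask_feret(sim$truth$cluster_mask, 10))
})

test_that("single-frame capture frequency over random phases matches 1 - T/dt", {
  # T = 15, dt = 110: p = 0.8636; check over independent movie seeds
  n <- 400
  caught <- vapply(seq_len(n), function(s) {
    sim <- gen_wave_movie(grid = c(2, 16), pixel_size = 10, cv = 10,
                          frame_interval = 110, noise_sd = 0, seed = s)
    # T = 150/10 = 15 ms; single-frame iff no frame boundary in
    # (phase, phase + T)
    ph <- sim$truth$start_phase
    floor((ph + sim$truth$t_traverse) / 110) == floor(ph / 110)
  }, logical(1))
  p <- capture_probability(15, 110)
  expect_lt(abs(mean(caught) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("spontaneous-trace generator honours period, amplitude and truth records", {
  # zero jitter, zero noise: all intervals equal the period
  g <- gen_spontaneous_traces(n_cells = 2, period_sd = 0, tau_sd = 0,
                              noise_sd = 0, seed = 4)
  tab <- transient_table(g$traces)
  expect_true(all(abs(tab$median_interval_ms - 1000) <= 20))  # one sample
  # peak count equals generated count
  expect_equal(tab$n_peaks,
               vapply(g$truth, function(t) length(t$onsets), integer(1)))
  # noiseless, well-separated transients: the peak equals the generated
  # amplitude up to sub-sample phase
  iso <- gen_spontaneous_traces(n_cells = 1, period_mean = 3000,
                                period_sd = 0, tau_sd = 0, noise_sd = 0,
                                seed = 4)
  tr <- iso$traces
  expect_lte(max(tr$value), 200 + 1e-6)
  expect_gte(max(tr$value), 100 + 100 * exp(-20 / 408))
  # analytic CaT50 stored on the truth
  expect_equal(g$truth[[1]]$cat50_analytic, g$truth[[1]]$tau_decay * log(2))
  # duration precondition
  expect_error(gen_spontaneous_traces(n_cells = 1, duration = 1),
               "duration")
})

test_that("cell-image generator footprint matches its analytic descriptors", {
  rod <- gen_cell_image(cell_image_truth(100, 20), pixel_size = 0.4,
                        noise_sd = 0)
  d <- descriptors(rod$mask, 0.4)
  tt <- rod$truth$descriptor_truth
  expect_equal(d$area, tt$area, tolerance = 0.02)
  expect_equal(d$aspect_ratio, tt$aspect_ratio, tolerance = 0.05)
  expect_equal(d$feret, tt$feret, tolerance = 0.02)
  circ <- gen_cell_image(cell_image_truth(50, 50), pixel_size = 0.4,
                         noise_sd = 0)
  expect_equal(descriptors(circ$mask, 0.4)$circularity, 1, tolerance = 0.03)
  # anti-aliasing guard
  expect_error(gen_cell_image(cell_image_truth(100, 20,
                                               striation_period = 1.0),
                              pixel_size = 0.3), "alias")
})

test_that("generated striation has the requested spatial period (FFT oracle)", {
  g <- gen_cell_image(cell_image_truth(100, 20, striation_period = 2.0),
                      pixel_size = 0.2, noise_sd = 0)
  # oracle: raw periodogram of the central image row inside the mask
  mid <- which(rowSums(g$mask) == max(rowSums(g$mask)))[1]
  sel <- which(g$mask[mid, ])
  sel <- sel[10:(length(sel) - 10)]        # avoid cap edges
  prof <- g$image[mid, sel]
  prof <- prof - mean(prof)
  pw <- Mod(stats::fft(prof))^2
  pw <- pw[2:floor(length(prof) / 2)]
  freq <- (2:floor(length(prof) / 2) - 1) / (length(prof) * 0.2)
  per <- 1 / freq[which.max(pw)]
  bin <- 1 / (length(prof) * 0.2)
  expect_lt(abs(1 / per - 1 / 2.0), 1.5 * bin)
})

test_that("ephys sweeps scale with capacitance and expose exact densities", {
  t1 <- ephys_truth(cm = 15)
  t2 <- ephys_truth(cm = 30)
  s1 <- gen_ephys_sweeps(t1, noise_sd = 0)
  s2 <- gen_ephys_sweeps(t2, noise_sd = 0)
  # doubling cm doubles every current sample, densities unchanged
  expect_equal(s2$sweeps$current_pA, 2 * s1$sweeps$current_pA,
               tolerance = 1e-12)
  expect_identical(t1$density_truth, t2$density_truth)
  # null outward component gives a zero plateau at every step
  t0 <- ephys_truth(g_out = 0, cm = 20)
  s0 <- gen_ephys_sweeps(t0, protocol_iv(), sample_interval = 1,
                         noise_sd = 0)
  expect_true(all(abs(s0$sweeps$current_pA) < 1e-12))
  # fast-component resolution guard
  expect_error(gen_ephys_sweeps(t1, sample_interval = 3), "resolve")
})

test_that("truth records round-trip through JSON unchanged", {
  tr <- transient_truth(period = 1000, tau_decay = 408, seed = 7)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(tr), f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$tau_decay, tr$tau_decay)
  expect_equal(back$cat50_analytic, tr$cat50_analytic)
  expect_equal(back$period_true, tr$period_true)
})

test_that("generator parameter validation rejects impossible inputs", {
  expect_error(gen_wave_movie(grid = c(0, 5), pixel_size = 10, cv = 20,
                              frame_interval = 110), "grid")
  expect_error(gen_wave_movie(grid = c(4, 5), pixel_size = 10, cv = -1,
                              frame_interval = 110), "cv")
  expect_error(gen_wave_movie(grid = c(4, 5), pixel_size = 10, cv = 20,
                              frame_interval = 0), "frame_interval")
})
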