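test_that("a 1 px/frame marching pulse maps to activation times 0..9 frames", {
  stk <- marching_pulse_stack(npx = 10)
  map <- activation_map(stk, theta = 0.10)
  expect_equal(as.numeric(map$times_ms[1, ]), (0:9) * 110)
  expect_equal(map$n_activated, 10)
})

test_that("constant movies give no activations; a flash activates all at 0", {
  cst <- frame_stack(array(100, dim = c(10, 3, 3)), 110, 10)
  m0 <- activation_map(cst, theta = 0.10)
  expect_equal(m0$n_activated, 0)
  fr <- array(100, dim = c(12, 3, 3)); fr[6:8, , ] <- 200
  fl <- activation_map(frame_stack(fr, 110, 10), theta = 0.10)
  expect_true(all(fl$times_ms == 0))
})

test_that("activation map is invariant to global intensity scaling", {
  sim <- gen_wave_movie(grid = c(5, 20), pixel_size = 10, cv = 1,
                        frame_interval = 110, seed = 13)
  m1 <- activation_map(sim$stack, theta = 0.10)
  scaled <- frame_stack(sim$stack$frames * 3.7, 110, 10)
  m2 <- activation_map(scaled, theta = 0.10)
  expect_identical(m1$frames, m2$frames)
})

test_that("theta must be positive and is recorded on the map", {
  stk <- marching_pulse_stack()
  expect_error(activation_map(stk, theta = 0), "theta")
  expect_equal(activation_map(stk, theta = 0.2)$theta, 0.2)
})

test_that("space-time plots: slanted band for a wave, mirrored for a reversed path", {
  stk <- marching_pulse_stack(npx = 8)
  path <- cbind(1, 1:8)
  st <- space_time_plot(stk, path)
  expect_equal(dim(st), c(8, 30))
  # activation (first bright frame) advances one frame per pixel
  first_on <- apply(unclass(st), 1, function(r) which(r > 0.5)[1])
  expect_equal(diff(first_on), rep(1, 7))
  rev_st <- space_time_plot(stk, path[8:1, ])
  expect_equal(rev_st[, ], st[8:1, ][, ])
  # constant movie: constant rows
  cst <- frame_stack(array(100, dim = c(5, 3, 3)), 110, 10)
  expect_true(all(space_time_plot(cst, cbind(1:3, 1)) ==
                    space_time_plot(cst, cbind(1:3, 1))[, 1]))
  expect_error(space_time_plot(stk, cbind(c(1, 1), c(99, 100))), "outside")
})

test_that("event classification separates single- and multi-frame propagation", {
  stk <- marching_pulse_stack(npx = 10)
  map <- activation_map(stk, theta = 0.10)
  ev <- classify_event(map)
  expect_equal(ev$outcome, "multi_frame")
  expect_equal(ev$frames_spanned, 10)
  # simultaneous flash: single frame
  fr <- array(100, dim = c(12, 2, 5)); fr[6, , ] <- 200
  fl <- activation_map(frame_stack(fr, 110, 10), theta = 0.10)
  ef <- classify_event(fl)
  expect_equal(ef$outcome, "single_frame")
  expect_equal(ef$frames_spanned, 1)
  # two adjacent frames -> multi_frame, span 2
  fr2 <- array(100, dim = c(12, 1, 4))
  fr2[6, 1, 1:2] <- 200; fr2[7, 1, 3:4] <- 200
  e2 <- classify_event(activation_map(frame_stack(fr2, 110, 10), 0.10))
  expect_equal(e2$outcome, "multi_frame")
  expect_equal(e2$frames_spanned, 2)
  # fewer than two activated pixels is an error
  fr3 <- array(100, dim = c(12, 1, 4)); fr3[6, 1, 1] <- 200
  expect_error(classify_event(activation_map(frame_stack(fr3, 110, 10), 0.1)),
               "2 activated")
})

test_that("gradient CV recovers the true velocity for multi-frame waves", {
  for (cv in c(0.6, 1.0, 1.5)) {
    sim <- gen_wave_movie(grid = c(8, 40), pixel_size = 10, cv = cv,
                          frame_interval = 110, seed = round(100 * cv))
    est <- estimate_cv(activation_map(sim$stack, theta = 0.10))
    expect_equal(est, cv, tolerance = 0.1)
  }
})

test_that("multi-beat movies split into one window per beat", {
  sim <- simulate_recording(preset("demo-slow-wave"), seed = 3)
  w <- split_beats(sim$stack)
  expect_length(w, 3)
  maps <- lapply(seq_along(w), function(i)
    activation_map(sim$stack, beat_window = w[[i]], beat_index = i))
  expect_equal(vapply(maps, function(m) m$beat_index, integer(1)), 1:3)
  expect_true(all(vapply(maps, function(m) m$n_activated, numeric(1)) > 0))
})

test_that("synchronization is true for a coupled wave, false for a phase-shifted roi", {
  # monolayer wave crossing both groups within one frame interval
  sim <- gen_wave_movie(grid = c(6, 20), pixel_size = 10, cv = 2,
                        frame_interval = 110, noise_sd = 0, seed = 8)
  lab <- matrix(1L, 6, 20); lab[3:4, 9:12] <- 2L
  rois <- roi_set(lab, groups = c("1" = "monolayer", "2" = "MSC"))
  map <- activation_map(sim$stack, theta = 0.10)
  sy <- synchronization(map, rois)
  expect_true(sy$synchronized)
  expect_true(all(sy$offsets$offset_ms <= 110))

  # give the embedded roi an independent beat 3 frames later
  fr <- sim$stack$frames
  msc <- lab == 2L
  for (f in seq_len(dim(fr)[1]))
    fr[f, , ][msc] <- 100
  shift <- 3L
  src <- sim$stack$frames
  for (f in seq_len(dim(fr)[1] - shift))
    fr[f + shift, , ][msc] <- src[f, , ][msc]
  map2 <- activation_map(frame_stack(fr, 110, 10), theta = 0.10)
  sy2 <- synchronization(map2, rois)
  expect_false(sy2$synchronized)
  off2 <- sy2$offsets$offset_ms[sy2$offsets$group == "MSC"]
  expect_gte(off2, 3 * 110 - 110)

  # a single group against itself has offset zero
  solo <- roi_set(matrix(1L, 6, 20), groups = c("1" = "all"))
  expect_equal(synchronization(map, solo)$offsets$offset_ms, 0)
})
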