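#' Simulate a propagating calcium wave movie
#'
#' Generates a fluorescence movie of an excitation wave crossing a cell
#' cluster at a known conduction velocity, sampled at the camera frame
#' interval, together with a ground-truth record. Each pixel's trace is
#' `baseline + transient(t - onset)` where the onset equals the distance
#' along the propagation direction divided by `cv`, shifted by a wave start
#' phase drawn uniformly in `[0, frame_interval)` — the implicit sampling
#' assumption behind the frame-censored capture probability
#' `p = max(0, 1 - T / dt)`.
#'
#' `cv` is in mm/s, which conveniently equals um/ms, so
#' `onset_ms = distance_um / cv`.
#'
#' @param grid `(ny, nx)` frame size in pixels.
#' @param pixel_size Pixel edge length, um.
#' @param cv True conduction velocity, mm/s (`Inf` gives a simultaneous
#'   full-cluster flash).
#' @param frame_interval Camera frame interval, ms.
#' @param n_beats Number of waves, spaced by the transient period.
#' @param transient A [transient_truth()] describing the per-pixel waveform.
#' @param noise_sd Additive Gaussian camera noise, intensity units.
#' @param seed Integer seed.
#' @param wave `"planar"` (front advancing along +x) or `"target"`
#'   (circular wave from the cluster centre).
#' @param cluster Optional logical mask of the active cluster; default all
#'   pixels.
#' @param start_phase Wave start phase in ms; default drawn uniformly in
#'   `[0, frame_interval)`.
#' @param n_frames Movie length; default just covers the last beat's decay.
#' @return A list with elements `stack` ([frame_stack]) and `truth`
#'   (class `wave_movie_truth`: `cv_true`, `activation_true` in ms with the
#'   wave entering the cluster at 0, `cluster_mask`, `cluster_length` um,
#'   `t_traverse` ms, `start_phase` ms, `period`, `seed`).
#' @examples
#' sim <- gen_wave_movie(grid = c(8, 40), pixel_size = 10, cv = 20,
#'                       frame_interval = 110, seed = 1)
#' sim$truth$t_traverse   # cluster traversal time, ms
#' @export
gen_wave_movie <- function(grid, pixel_size, cv, frame_interval,
                           n_beats = 1, transient = transient_truth(),
                           noise_sd = 2, seed = NULL,
                           wave = c("planar", "target"), cluster = NULL,
                           start_phase = NULL, n_frames = NULL) {
  wave <- match.arg(wave)
  if (length(grid) != 2L || any(grid < 1))
    stop("`grid` must be positive (ny, nx)", call. = FALSE)
  if (!is.numeric(cv) || cv <= 0) stop("`cv` must be > 0", call. = FALSE)
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(pixel_size, "pixel_size")
  ny <- grid[1]; nx <- grid[2]
  if (is.null(cluster)) cluster <- matrix(TRUE, ny, nx)
  if (!all(dim(cluster) == c(ny, nx)))
    stop("`cluster` must match `grid`", call. = FALSE)

  with_seed(seed, {
    if (is.null(start_phase)) start_phase <- stats::runif(1, 0, frame_interval)

    xs <- (col(cluster) - 1) * pixel_size
    ys <- (row(cluster) - 1) * pixel_size
    dist_um <- switch(wave,
      planar = xs,
      target = {
        cx <- mean(range(xs[cluster])); cy <- mean(range(ys[cluster]))
        sqrt((xs - cx)^2 + (ys - cy)^2)
      })
    act <- dist_um / cv                      # ms; 0 where cv = Inf
    act[!cluster] <- NA_real_
    act <- act - min(act, na.rm = TRUE)      # wave enters the cluster at 0
    t_traverse <- diff(range(act, na.rm = TRUE))

    period <- transient$period_true
    tail_ms <- transient$rise_time + 4 * transient$tau_decay
    if (is.null(n_frames))
      n_frames <- ceiling((start_phase + (n_beats - 1) * period +
                             t_traverse + tail_ms) / frame_interval) + 2
    t_frames <- (seq_len(n_frames) - 1) * frame_interval

    frames <- array(transient$baseline, dim = c(n_frames, ny, nx))
    on_pix <- act + start_phase              # beat-1 onset per pixel, ms
    idx <- which(cluster)
    for (f in seq_len(n_frames)) {
      sl <- matrix(0, ny, nx)
      for (b in seq_len(n_beats)) {
        tt <- t_frames[f] - (on_pix + (b - 1) * period)
        v <- numeric(length(idx))
        sel <- !is.na(tt[idx]) & tt[idx] >= 0
        if (any(sel)) v[sel] <- transient_shape(tt[idx][sel], transient)
        sl[idx] <- sl[idx] + v
      }
      frames[f, , ] <- frames[f, , ] + sl
    }
    if (noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
    frames[frames < 0] <- 0

    truth <- structure(
      list(cv_true = cv, activation_true = act, cluster_mask = cluster,
           cluster_length = mask_feret(cluster, pixel_size),
           t_traverse = t_traverse, start_phase = start_phase,
           period = period, seed = if (is.null(seed)) NA_integer_ else seed),
      class = "wave_movie_truth")
    list(stack = frame_stack(frames, frame_interval, pixel_size),
         truth = truth)
  })
}

#' Simulate spontaneous calcium transient traces for a cell population
#'
#' Regular cells fire with Gaussian-jittered periods around `period_mean`;
#' irregular cells fire rarely, with inter-event intervals drawn above
#' 5000 ms. The decay constant varies across cells
#' (`tau_decay + N(0, tau_sd)`), giving the population a Gaussian spread of
#' CaT50 values; every cell's truth record carries its analytic
#' `cat50 = tau * log(2)`.
#'
#' Defaults emulate single-cell recordings: 30 s duration and 20 ms
#' sampling (faster than the 110 ms wide-field conduction movies), 1 s mean
#' period for regular cells.
#'
#' @param n_cells Number of cells.
#' @param period_mean,period_sd Mean and jitter of the regular firing
#'   period, ms.
#' @param tau_decay Population mean decay constant, ms.
#' @param tau_sd Cell-to-cell SD of the decay constant, ms.
#' @param irregular_fraction Fraction of cells with rare (> 5 s) events.
#' @param duration Recording length, s.
#' @param frame_interval Sampling interval, ms.
#' @param amplitude,baseline Transient amplitude and diastolic level,
#'   intensity units.
#' @param noise_sd Additive Gaussian noise, intensity units.
#' @param seed Integer seed.
#' @return A list with `traces` (tibble `id`, `time_ms`, `value`) and
#'   `truth` (one [transient_truth()]-like record per cell, augmented with
#'   `cell_id`, `regular`, `onsets` and cell-specific `tau_decay`).
#' @export
gen_spontaneous_traces <- function(n_cells = 26, period_mean = 1000,
                                   period_sd = 75, tau_decay = 408,
                                   tau_sd = 40, irregular_fraction = 0,
                                   duration = 30, frame_interval = 20,
                                   amplitude = 100, baseline = 100,
                                   noise_sd = 1, seed = NULL) {
  stopifnot(n_cells >= 1, irregular_fraction >= 0, irregular_fraction <= 1)
  dur_ms <- duration * 1000
  if (dur_ms < 2 * period_mean)
    stop("`duration` too short: must cover at least two mean periods",
         call. = FALSE)
  with_seed(seed, {
    n_irr <- round(irregular_fraction * n_cells)
    is_irr <- seq_len(n_cells) <= n_irr     # deterministic split given seed
    t_ms <- seq(0, dur_ms, by = frame_interval)
    out <- vector("list", n_cells)
    truths <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      tau_i <- max(50, tau_decay + stats::rnorm(1, 0, tau_sd))
      tr <- transient_truth(period = period_mean, tau_decay = tau_i,
                            amplitude = amplitude, baseline = baseline)
      onsets <- if (is_irr[i]) {
        on <- stats::runif(1, 0, 2000); res <- c()
        while (on < dur_ms - 4 * tau_i) {
          res <- c(res, on)
          on <- on + stats::runif(1, 5500, 9000)
        }
        res
      } else {
        on <- stats::runif(1, 0, period_mean); res <- c()
        while (on < dur_ms - 2 * tau_i) {
          res <- c(res, on)
          on <- on + max(period_mean / 2,
                         period_mean + stats::rnorm(1, 0, period_sd))
        }
        res
      }
      if (length(onsets) < 1L)
        stop("duration too short to contain one full transient", call. = FALSE)
      v <- rep(baseline, length(t_ms))
      for (on in onsets) {
        tt <- t_ms - on
        sel <- tt >= 0
        v[sel] <- v[sel] + transient_shape(tt[sel], tr)
      }
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      v[v < 0] <- 0
      id <- sprintf("cell_%03d", i)
      out[[i]] <- tibble::tibble(id = id, time_ms = t_ms, value = v)
      tr$cell_id <- id
      tr$tau_decay <- tau_i
      tr$cat50_analytic <- tau_i * log(2)
      tr$regular <- !is_irr[i]
      tr$onsets <- onsets
      tr$seed <- if (is.null(seed)) NA_integer_ else seed
      truths[[i]] <- tr
    }
    list(traces = dplyr::bind_rows(out), truth = truths,
         frame_interval = frame_interval)
  })
}

#' Render a synthetic cell image with optional sarcomeric striation
#'
#' Rasterises a rotated stadium-shaped cell (rectangle with semicircular
#' caps; a circle when `length == width`). When the truth carries a
#' striation period, intensity inside the cell is modulated sinusoidally
#' along the major axis at that period, mimicking alpha-actinin banding.
#' The returned mask is the exact generating footprint.
#'
#' @param truth A [cell_image_truth()].
#' @param pixel_size Pixel edge length, um; the striation period must span
#'   at least 4 pixels (anti-aliasing guard).
#' @param noise_sd Additive Gaussian noise, intensity units.
#' @param intensity,background Foreground/background mean intensities.
#' @param modulation Striation modulation depth (fraction of `intensity`).
#' @param margin Canvas padding around the cell, um.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix), `mask` (logical matrix)
#'   and `truth`.
#' @export
gen_cell_image <- function(truth, pixel_size = 0.2, noise_sd = 2,
                           intensity = 150, background = 10,
                           modulation = 0.4, margin = 5, seed = NULL) {
  stopifnot(inherits(truth, "cell_image_truth"))
  if (!is.na(truth$striation_period) &&
      truth$striation_period < 4 * pixel_size)
    stop("striation period below 4 pixels would alias; ",
         "use a smaller pixel_size", call. = FALSE)
  ext <- truth$length + 2 * margin
  n <- ceiling(ext / pixel_size)
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  th <- truth$orientation * pi / 180
  # pixel-centre coordinates in the cell frame (s along major axis, um)
  xs <- (col(matrix(0, n, n)) - cx) * pixel_size
  ys <- -(row(matrix(0, n, n)) - cy) * pixel_size   # row down -> y up
  s <- xs * cos(th) + ys * sin(th)
  q <- -xs * sin(th) + ys * cos(th)
  half <- (truth$length - truth$width) / 2          # cap-centre offset
  ds <- pmax(abs(s) - half, 0)
  mask <- sqrt(ds^2 + q^2) <= truth$width / 2
  with_seed(seed, {
    img <- matrix(background, n, n)
    base <- intensity
    if (!is.na(truth$striation_period)) {
      mod <- 1 + modulation * sin(2 * pi * s / truth$striation_period)
      img[mask] <- base * mod[mask]
    } else {
      img[mask] <- base
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
    list(image = img, mask = mask, truth = truth)
  })
}
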