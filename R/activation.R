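#' Adaptive-threshold activation map
#'
#' Implements per-pixel adaptive thresholding: a pixel activates at the
#' first frame (within the beat window) whose intensity exceeds its own
#' temporal mean brightness by the fraction `theta`, i.e.
#' `I > (1 + theta) * mean_t(I)`. Because each pixel is compared against
#' its own mean, the map is invariant to global intensity scaling and to
#' static spatial inhomogeneity of illumination or dye loading, which a
#' single global threshold is not.
#'
#' The pixel mean is computed over the full recording (not just the beat
#' window), which is stable across beats. Activation times are converted
#' to ms via the frame interval and re-zeroed to the earliest activated
#' pixel. Pixels that never cross threshold carry `NA` — distinct from an
#' activation at 0 ms.
#'
#' @param stack A [frame_stack].
#' @param theta Threshold fraction above the pixel's temporal mean
#'   (mandatory in spirit: it is always recorded in the result; default
#'   0.10).
#' @param beat_window Integer frame range (e.g. `5:40`) containing one
#'   upstroke; default all frames.
#' @param beat_index Beat number recorded in the result.
#' @param median_filter Apply a 3x3 spatial median prefilter to each frame
#'   before thresholding (off by default; suppresses salt noise).
#' @param normalized Threshold dF/F-normalised intensity instead of raw
#'   (`I/mean - 1 > theta` is identical to raw mode; this flag instead
#'   thresholds `(I - F0)/F0` against a rolling-percentile `F0`).
#' @return An object of class `activation_map`: `times_ms` (matrix, NA =
#'   never activated), `frames` (first-crossing frame index, 1-based),
#'   `theta`, `beat_index`, `frame_interval`, `pixel_size`, `n_activated`.
#'   An empty map (no pixel crossed) is flagged via `n_activated = 0`, not
#'   an error.
#' @export
activation_map <- function(stack, theta = 0.10, beat_window = NULL,
                           beat_index = 1L, median_filter = FALSE,
                           normalized = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  fr <- stack$frames
  nf <- dim(fr)[1]
  if (is.null(beat_window)) beat_window <- seq_len(nf)
  beat_window <- intersect(as.integer(beat_window), seq_len(nf))
  if (!length(beat_window)) stop("empty beat window", call. = FALSE)
  if (median_filter) {
    for (f in seq_len(nf))
      fr[f, , ] <- spatial_median3(fr[f, , ])
  }
  ny <- dim(fr)[2]; nx <- dim(fr)[3]
  pix_mean <- apply(fr, c(2, 3), mean)
  first <- matrix(NA_real_, ny, nx)
  if (normalized) {
    # dF/F against a per-pixel rolling-percentile baseline
    for (r in seq_len(ny)) for (c in seq_len(nx)) {
      ts <- fr[, r, c]
      f0 <- rolling_baseline(ts, stack$frame_interval)
      dff <- (ts - f0) / pmax(f0, .Machine$double.eps)
      hit <- beat_window[dff[beat_window] > theta]
      if (length(hit)) first[r, c] <- hit[1]
    }
  } else {
    thr <- (1 + theta) * pix_mean
    sub <- fr[beat_window, , , drop = FALSE]
    over <- sweep(sub, c(2, 3), thr, FUN = ">")
    anyhit <- apply(over, c(2, 3), any)
    idx <- apply(over, c(2, 3), which.max)  # first TRUE (1 if none -> masked)
    first[anyhit] <- beat_window[idx[anyhit]]
  }
  fin <- is.finite(first)
  times <- (first - if (any(fin)) min(first[fin]) else 0) *
    stack$frame_interval
  structure(list(times_ms = times, frames = first, theta = theta,
                 beat_index = as.integer(beat_index),
                 frame_interval = stack$frame_interval,
                 pixel_size = stack$pixel_size,
                 n_activated = sum(fin)),
            class = "activation_map")
}

spatial_median3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    rr <- max(1, r - 1):min(ny, r + 1)
    cc <- max(1, c - 1):min(nx, c + 1)
    out[r, c] <- stats::median(m[rr, cc])
  }
  out
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> beat %d | theta = %g | %d/%d px activated | span %s\n",
    x$beat_index, x$theta, x$n_activated, length(x$times_ms),
    if (x$n_activated)
      paste0(diff(range(x$frames, na.rm = TRUE)) + 1, " frame(s)")
    else "none"))
  invisible(x)
}

#' Split a multi-beat movie into beat windows
#'
#' Beat windows are delimited by the peaks of the global mean-intensity
#' trace; each window runs from the midpoint before a peak to the midpoint
#' after it.
#'
#' @param stack A [frame_stack].
#' @param ... Passed to [detect_transients()].
#' @return A list of integer frame ranges, one per detected beat.
#' @export
split_beats <- function(stack, ...) {
  tr <- fluor_trace(apply(stack$frames, 1, mean), stack$frame_interval,
                    roi_id = "global")
  m <- detect_transients(tr, ...)
  pk <- m$peak_frames
  if (!length(pk)) return(list())
  nf <- n_frames(stack)
  bounds <- c(1L, if (length(pk) > 1) floor((pk[-1] + pk[-length(pk)]) / 2),
              nf)
  lapply(seq_along(pk), function(i) bounds[i]:bounds[i + 1])
}

#' Space-time plot along a pixel path
#'
#' Row i of the result is the time series of path pixel i, normalised per
#' row to `[0, 1]`; a propagating plane wave appears as a slanted
#' activation band whose slope is the inverse velocity.
#'
#' @param stack A [frame_stack].
#' @param line Two-column matrix of `(row, col)` pixel coordinates (>= 2).
#' @return An object of class `space_time` (matrix position x time with
#'   attributes `frame_interval`, `pixel_size`).
#' @export
space_time_plot <- function(stack, line) {
  stopifnot(inherits(stack, "frame_stack"))
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("path needs >= 2 pixels", call. = FALSE)
  d <- dim(stack$frames)
  if (any(line[, 1] < 1 | line[, 1] > d[2] | line[, 2] < 1 | line[, 2] > d[3]))
    stop("path outside image", call. = FALSE)
  m <- t(vapply(seq_len(nrow(line)), function(i)
    stack$frames[, line[i, 1], line[i, 2]], numeric(d[1])))
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  m <- (m - rng[1, ]) / span
  structure(m, class = c("space_time", "matrix"),
            frame_interval = stack$frame_interval,
            pixel_size = stack$pixel_size)
}

#' Classify a propagation event as single- or multi-frame
#'
#' `frames_spanned` is `max - min` activation frame within the cluster
#' plus one; the event is `single_frame` iff the whole wavefront was
#' captured within one frame — the censored outcome whose probability is
#' `max(0, 1 - T/dt)`.
#'
#' @param map An [activation_map].
#' @param cluster Logical mask (or [roi_set] + `label`) of the cluster.
#' @param pixel_size Pixel size, um; default from the map.
#' @param label Roi label when `cluster` is a [roi_set].
#' @param beat Beat number to report.
#' @return A tibble row (class `propagation_event`): `beat`, `outcome`,
#'   `frames_spanned`, `cluster_length_um`, `delta_t_ms`.
#' @export
classify_event <- function(map, cluster = NULL, pixel_size = NULL,
                           label = 1L, beat = map$beat_index) {
  stopifnot(inherits(map, "activation_map"))
  if (is.null(pixel_size)) pixel_size <- map$pixel_size
  if (is.null(cluster)) cluster <- matrix(TRUE, nrow(map$frames),
                                          ncol(map$frames))
  if (inherits(cluster, "roi_set")) cluster <- roi_mask(cluster, label)
  act <- map$frames[cluster]
  act <- act[is.finite(act)]
  if (length(act) < 2L)
    stop("fewer than 2 activated pixels in cluster: no propagation to classify",
         call. = FALSE)
  span <- diff(range(act)) + 1
  tibble::new_tibble(tibble::tibble(
    beat = as.integer(beat),
    outcome = if (span == 1) "single_frame" else "multi_frame",
    frames_spanned = span,
    cluster_length_um = mask_feret(cluster, pixel_size),
    delta_t_ms = map$frame_interval), class = "propagation_event")
}

#' Conduction velocity from the activation-map gradient
#'
#' Fits a plane `t(x, y) = a + gx * x + gy * y` to the finite activation
#' times by least squares; CV is the inverse gradient magnitude
#' `1 / |(gx, gy)|` in mm/s (um/ms). Reliable when the wavefront spans at
#' least ~3 frames.
#'
#' @param map An [activation_map].
#' @param mask Optional logical mask restricting the fit.
#' @return CV estimate in mm/s (`NA` when degenerate).
#' @export
estimate_cv <- function(map, mask = NULL) {
  stopifnot(inherits(map, "activation_map"))
  t_ms <- map$times_ms
  keep <- is.finite(t_ms)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 3L) return(NA_real_)
  x_um <- (col(t_ms)[keep] - 1) * map$pixel_size
  y_um <- (row(t_ms)[keep] - 1) * map$pixel_size
  fit <- stats::lm.fit(cbind(1, x_um, y_um), t_ms[keep])
  g <- sqrt(sum(fit$coefficients[2:3]^2))
  if (!is.finite(g) || g <= 0) return(NA_real_)
  1 / g
}

#' Co-culture synchronization assessment
#'
#' Compares the median activation time of each named roi group against a
#' reference group; the layer is synchronized when every offset is within
#' the tolerance (default one frame interval).
#'
#' @param map An [activation_map].
#' @param groups A [roi_set] with named groups (>= 2 with activated
#'   pixels, unless comparing a single group with itself).
#' @param tolerance Offset tolerance, ms; default the frame interval.
#' @param reference Name of the reference group; default the first.
#' @return A list with `offsets` (tibble `group`, `n_pixels`,
#'   `median_time_ms`, `offset_ms`, `participating`) and `synchronized`
#'   (flag; `FALSE` when any group has no activated pixels).
#' @export
synchronization <- function(map, groups, tolerance = NULL,
                            reference = NULL) {
  stopifnot(inherits(map, "activation_map"), inherits(groups, "roi_set"))
  if (is.null(tolerance)) tolerance <- map$frame_interval
  gmap <- groups$groups
  if (is.null(gmap)) {
    ids <- sort(unique(groups$labels[groups$labels > 0L]))
    gmap <- stats::setNames(paste0("roi_", ids), as.character(ids))
  }
  names_u <- unique(unname(gmap))
  if (is.null(reference)) reference <- names_u[1]
  med <- function(gname) {
    labs <- as.integer(names(gmap)[gmap == gname])
    m <- matrix(FALSE, nrow(groups$labels), ncol(groups$labels))
    for (l in labs) m <- m | groups$labels == l
    v <- map$times_ms[m]
    v <- v[is.finite(v)]
    list(n = length(v),
         med = if (length(v)) stats::median(v) else NA_real_)
  }
  rows <- lapply(names_u, function(g) {
    s <- med(g)
    tibble::tibble(group = g, n_pixels = s$n, median_time_ms = s$med)
  })
  tab <- dplyr::bind_rows(rows)
  ref_med <- tab$median_time_ms[tab$group == reference]
  tab$offset_ms <- abs(tab$median_time_ms - ref_med)
  tab$participating <- tab$n_pixels > 0L
  ok <- all(tab$participating) && all(tab$offset_ms <= tolerance, na.rm = TRUE)
  list(offsets = tab, synchronized = ok, tolerance_ms = tolerance,
       reference = reference)
}
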