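#' Ground-truth records for the synthetic generators
#'
#' Each generator returns, next to its artifact, a truth record holding the
#' exact quantities the analysis is supposed to recover. Truth records are
#' plain lists with a class tag and round-trip through [jsonlite] unchanged.
#'
#' @name synth_truth
NULL

#' @describeIn synth_truth Parameters of a spontaneous calcium transient:
#'   firing period (ms), exponential decay constant `tau_decay` (ms),
#'   amplitude and baseline (camera intensity units) and optional linear
#'   rise time. The analytic CaT50 under the peak-to-half-decay convention
#'   is `tau_decay * log(2)` and is stored as `cat50_analytic`.
#' @param period Mean firing period, ms (> 0).
#' @param tau_decay Exponential decay constant, ms (> 0).
#' @param amplitude Transient amplitude above baseline, intensity units.
#' @param baseline Diastolic fluorescence, intensity units.
#' @param rise_time Linear rise time, ms (0 = instantaneous upstroke).
#' @param seed Integer seed recorded with the truth.
#' @export
transient_truth <- function(period = 1000, tau_decay = 408, amplitude = 100,
                            baseline = 100, rise_time = 0, seed = NA_integer_) {
  check_positive_scalar(period, "period")
  check_positive_scalar(tau_decay, "tau_decay")
  check_positive_scalar(amplitude, "amplitude")
  stopifnot(baseline >= 0, rise_time >= 0)
  structure(
    list(period_true = period, tau_decay = tau_decay, amplitude = amplitude,
         baseline = baseline, rise_time = rise_time,
         cat50_analytic = tau_decay * log(2), seed = seed),
    class = "transient_truth")
}

#' @describeIn synth_truth Geometry of a synthetic cell image: length and
#'   width (um) of the stadium-shaped footprint, orientation (degrees,
#'   counter-clockwise from the x axis), sarcomere striation period (um,
#'   `NA` for unstriated cells) and the analytic shape descriptors implied
#'   by the geometry.
#' @param length,width Major/minor extent of the cell footprint, um.
#' @param orientation Major-axis orientation, degrees.
#' @param striation_period Striation period in um, or `NA` for none.
#' @export
cell_image_truth <- function(length = 100, width = 20, orientation = 0,
                             striation_period = NA_real_, seed = NA_integer_) {
  check_positive_scalar(length, "length")
  check_positive_scalar(width, "width")
  if (width > length) stop("`length` must be >= `width`", call. = FALSE)
  if (!is.na(striation_period) &&
      (striation_period < 1.0 || striation_period > 3.0))
    stop("striation_period must lie in [1, 3] um (sarcomere scale)",
         call. = FALSE)
  # stadium (rectangle + semicircular caps); a circle when length == width
  area <- width * (length - width) + pi * (width / 2)^2
  perim <- 2 * (length - width) + pi * width
  structure(
    list(length = length, width = width, orientation = orientation,
         striation_period = striation_period,
         descriptor_truth = list(
           area = area, aspect_ratio = length / width,
           circularity = 4 * pi * area / perim^2,
           fractal_dimension = 1.0, feret = length),
         seed = seed),
    class = "cell_image_truth")
}

#' @describeIn synth_truth Scales of the phenomenological current templates:
#'   `g_fast_in`, `g_slow_in` are the peak inward current densities
#'   (pA/pF) of the fast (sodium-like) and slow (L-type-calcium-like)
#'   components; `g_out` is the specific outward (potassium-like)
#'   conductance in pA/pF/mV relative to the reversal `e_rev_out`.
#'   `density_truth` holds peak current / capacitance exactly.
#' @param g_fast_in,g_slow_in Peak inward densities, pA/pF (>= 0).
#' @param g_out Outward specific conductance, pA/pF/mV (>= 0).
#' @param cm Membrane capacitance, pF; the cohort default range is 12-30 pF.
#' @param e_rev_out Outward-current reversal potential, mV.
#' @export
ephys_truth <- function(g_fast_in = 7.66, g_slow_in = 4.35,
                        g_out = 15.07 / 145, cm = 20, e_rev_out = -85,
                        seed = NA_integer_) {
  stopifnot(g_fast_in >= 0, g_slow_in >= 0, g_out >= 0)
  check_positive_scalar(cm, "cm")
  structure(
    list(g_fast_in = g_fast_in, g_slow_in = g_slow_in, g_out = g_out,
         cm = cm, e_rev_out = e_rev_out,
         density_truth = list(fast = -g_fast_in, slow = -g_slow_in,
                              out_per_mv = g_out),
         seed = seed),
    class = "ephys_truth")
}

# Evaluate one transient waveform at times `t` (ms) relative to its onset.
transient_shape <- function(t, truth) {
  v <- numeric(length(t))
  r <- truth$rise_time
  if (r > 0) {
    ris <- t >= 0 & t < r
    v[ris] <- truth$amplitude * t[ris] / r
  }
  dec <- t >= r
  v[dec] <- truth$amplitude * exp(-(t[dec] - r) / truth$tau_decay)
  v
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are reproducible and side-effect
# free.
with_seed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Maximal caliper (Feret) length of a binary mask
#'
#' Computed as the maximal pairwise distance between pixel centres on the
#' convex hull of the region, scaled by the pixel size.
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel edge length, um.
#' @return Feret diameter in um.
#' @export
mask_feret <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  if (nrow(idx) == 1L) return(0)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[h, , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  max(d) * pixel_size
}
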