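#' Fast and slow inward peak currents from a depolarising step
#'
#' Baseline (pre-step holding current) is subtracted, then the fast
#' (sodium-like) peak is the most negative current within `split_time` ms
#' of the step onset and the slow (L-type-calcium-like) peak the most
#' negative current after it. The time split is used because both
#' components are recorded in one protocol; 10 ms cleanly separates a
#' <10 ms transient from a >15 ms one.
#'
#' @param sweeps Sweep tibble (`sweep_id`, `time_ms`, `command_mV`,
#'   `current_pA`) or the list returned by [gen_ephys_sweeps()].
#' @param sweep_id Which sweep to analyse.
#' @param split_time Fast/slow split after step onset, ms.
#' @param baseline_ms Span before the step onset averaged for baseline
#'   subtraction.
#' @return A tibble row: `fast_peak_pA`, `slow_peak_pA`, `step_onset_ms`,
#'   `step_mV`.
#' @export
peak_inward <- function(sweeps, sweep_id = 1L, split_time = 10,
                        baseline_ms = 20) {
  sw <- as_sweep_table(sweeps)
  sw <- sw[sw$sweep_id == sweep_id, ]
  if (!nrow(sw)) stop("no such sweep: ", sweep_id, call. = FALSE)
  on <- step_onset(sw)
  if (is.na(on)) stop("step onset not found in protocol", call. = FALSE)
  if (max(sw$time_ms) - on < 50)
    stop("test step shorter than 50 ms", call. = FALSE)
  base <- mean(sw$current_pA[sw$time_ms < on & sw$time_ms >= on - baseline_ms])
  i <- sw$current_pA - base
  t <- sw$time_ms - on
  si <- stats::median(diff(sw$time_ms))
  # light smoothing before extremum picking, scaled to each component's
  # time course, so the minimum tracks the waveform rather than noise dips
  fast <- min(run_mean(i, max(1L, round(0.6 / si)))[t >= 0 & t <= split_time])
  slow <- min(run_mean(i, max(1L, round(5 / si)))[t > split_time])
  tibble::tibble(fast_peak_pA = fast, slow_peak_pA = slow,
                 step_onset_ms = on, step_mV = sw$command_mV[nrow(sw)])
}

# Centred running mean with window k (odd; shrunk at the edges).
run_mean <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2 == 0L) k <- k + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Last voltage transition of a sweep = onset of its test step.
step_onset <- function(sw) {
  ch <- which(diff(sw$command_mV) != 0)
  if (!length(ch)) return(NA_real_)
  sw$time_ms[ch[length(ch)] + 1L]
}

as_sweep_table <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$sweeps)) x <- x$sweeps
  need <- c("sweep_id", "time_ms", "command_mV", "current_pA")
  if (!all(need %in% names(x)))
    stop("sweeps need columns ", paste(need, collapse = ", "), call. = FALSE)
  x
}

#' Capacitance-normalised current density
#'
#' @param peak Peak current, pA.
#' @param cm Membrane capacitance, pF (> 0).
#' @return Current density, pA/pF.
#' @examples
#' density_pa_pf(-153.2, 20)   # -7.66
#' @export
density_pa_pf <- function(peak, cm) {
  check_positive_scalar(cm, "cm")
  peak / cm
}

#' I-V curve from a voltage-step family
#'
#' Per step, the current is averaged over the terminal `window` ms of the
#' test step (steady-state mode, the default) or taken as the extreme
#' value over the step (`mode = "peak"`); densities are current / cm,
#' points ordered by step voltage.
#'
#' @param sweeps Sweep tibble or [gen_ephys_sweeps()] result.
#' @param cm Membrane capacitance, pF.
#' @param window Terminal averaging window, ms.
#' @param baseline_ms Pre-step baseline span, ms.
#' @param mode `"steady"` or `"peak"`.
#' @return A tibble of I-V points: `voltage_mV`, `current_pA`,
#'   `current_density` (pA/pF).
#' @export
iv_curve <- function(sweeps, cm, window = 200, baseline_ms = 20,
                     mode = c("steady", "peak")) {
  mode <- match.arg(mode)
  check_positive_scalar(cm, "cm")
  sw <- as_sweep_table(sweeps)
  ids <- unique(sw$sweep_id)
  if (length(ids) < 3L) stop("need >= 3 steps for an I-V curve", call. = FALSE)
  rows <- lapply(ids, function(id) {
    s <- sw[sw$sweep_id == id, ]
    on <- step_onset(s)
    if (is.na(on)) stop("step onset not found in sweep ", id, call. = FALSE)
    dur <- max(s$time_ms) - on
    if (window > dur)
      stop("averaging window (", window, " ms) exceeds step duration (",
           dur, " ms)", call. = FALSE)
    base <- mean(s$current_pA[s$time_ms < on & s$time_ms >= on - baseline_ms])
    i <- s$current_pA - base
    t <- s$time_ms - on
    val <- if (mode == "steady") mean(i[t >= dur - window])
           else i[t >= 0][which.max(abs(i[t >= 0]))]
    tibble::tibble(voltage_mV = s$command_mV[nrow(s)], current_pA = val,
                   current_density = val / cm)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$voltage_mV), ]
}

#' Action-potential metrics including APD80
#'
#' Resting potential is the pre-stimulus mean; the AP start is the time of
#' maximal upstroke velocity (max dV/dt, the standard convention); APD80
#' runs from there to the first crossing of
#' `peak - 0.8 * (peak - resting)`, linearly interpolated. APD80 is by
#' construction invariant to additive voltage offsets and to scaling of
#' the amplitude.
#'
#' @param trace Tibble with `time_ms` and `vm_mV` (or numeric vector +
#'   `sample_interval`).
#' @param stim_time Stimulus time, ms.
#' @param sample_interval Required when `trace` is a bare numeric vector.
#' @param min_amplitude Minimal depolarisation (mV) above resting to call
#'   an AP.
#' @return A tibble row: `resting_mV`, `peak_mV`, `amplitude_mV`,
#'   `apd80_ms`, `has_ap`. A flat trace yields `has_ap = FALSE`, not an
#'   error.
#' @export
apd80 <- function(trace, stim_time, sample_interval = NULL,
                  min_amplitude = 20) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(sample_interval))
      stop("supply `sample_interval` with a bare vector", call. = FALSE)
    trace <- tibble::tibble(
      time_ms = (seq_along(trace) - 1) * sample_interval, vm_mV = trace)
  }
  stopifnot(all(c("time_ms", "vm_mV") %in% names(trace)))
  t <- trace$time_ms; v <- trace$vm_mV
  pre <- t < stim_time
  if (!any(pre)) stop("no pre-stimulus samples", call. = FALSE)
  resting <- mean(v[pre])
  post <- which(t >= stim_time)
  pk_i <- post[which.max(v[post])]
  peak <- v[pk_i]
  ampl <- peak - resting
  no_ap <- tibble::tibble(resting_mV = resting, peak_mV = peak,
                          amplitude_mV = ampl, apd80_ms = NA_real_,
                          has_ap = FALSE)
  if (ampl < min_amplitude) return(no_ap)
  dv <- diff(v) / diff(t)
  up_candidates <- post[post < pk_i]
  if (!length(up_candidates)) return(no_ap)
  up_i <- up_candidates[which.max(dv[pmin(up_candidates,
                                          length(dv))])]
  t_up <- (t[up_i] + t[up_i + 1L]) / 2     # midpoint of the steepest step
  level <- peak - 0.8 * ampl
  apd <- NA_real_
  for (j in (pk_i + 1L):length(v)) {
    if (v[j] < level && v[j - 1L] >= level) {
      f <- (v[j - 1L] - level) / (v[j - 1L] - v[j])
      apd <- t[j - 1L] + f * (t[j] - t[j - 1L]) - t_up
      break
    }
  }
  tibble::tibble(resting_mV = resting, peak_mV = peak, amplitude_mV = ampl,
                 apd80_ms = apd, has_ap = TRUE)
}

#' Density table for a cohort of cells
#'
#' Runs [peak_inward()] on each cell's inward-protocol sweeps and
#' [iv_curve()] on its outward family, and normalises by that cell's
#' capacitance.
#'
#' @param recordings List of per-cell lists with elements `inward`
#'   (sweeps), `outward` (sweeps, optional), `cm` (pF).
#' @param split_time Fast/slow split, ms.
#' @return A tibble: `cell`, `component`, `peak_pA`, `cm_pF`,
#'   `density_pA_pF`.
#' @export
density_table <- function(recordings, split_time = 10) {
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    out <- list()
    if (!is.null(rec$inward)) {
      pk <- peak_inward(rec$inward, split_time = split_time)
      out$fast <- tibble::tibble(cell = i, component = "fast_inward",
                                 peak_pA = pk$fast_peak_pA, cm_pF = rec$cm,
                                 density_pA_pF = pk$fast_peak_pA / rec$cm)
      out$slow <- tibble::tibble(cell = i, component = "slow_inward",
                                 peak_pA = pk$slow_peak_pA, cm_pF = rec$cm,
                                 density_pA_pF = pk$slow_peak_pA / rec$cm)
    }
    if (!is.null(rec$outward)) {
      iv <- iv_curve(rec$outward, cm = rec$cm)
      mx <- iv[which.max(iv$current_density), ]
      out$out <- tibble::tibble(cell = i, component = "outward",
                                peak_pA = mx$current_pA, cm_pF = rec$cm,
                                density_pA_pF = mx$current_density)
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}
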