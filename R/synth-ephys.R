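#' Voltage-step protocol descriptions
#'
#' A protocol is a tibble of contiguous voltage segments per sweep
#' (`sweep_id`, `segment`, `v_mV`, `dur_ms`) with an attribute
#' `components` naming which phenomenological current components the
#' protocol isolates (`"fast"`/`"slow"` inward, `"out"`ward).
#'
#' `protocol_inward_step()` is the depolarising step used for the fast
#' sodium-like and slow calcium-like inward currents: holding, a -30 mV
#' prestep (150 ms) and a 0 mV test step (300 ms).
#' `protocol_iv()` is the outward-current family: steps from `from` to
#' `to` mV in `by` mV increments (default -30 to +60 by 15, 2.5 s).
#' `protocol_kv_step()` is the long outward step family (-40 to +60, 5 s).
#'
#' @param holding_mV,holding_ms Holding segment before the prestep.
#' @param prestep_mV,prestep_ms Conditioning prestep.
#' @param step_mV,step_ms Test step.
#' @return A tibble with attribute `components`.
#' @export
protocol_inward_step <- function(holding_mV = -80, holding_ms = 50,
                                 prestep_mV = -30, prestep_ms = 150,
                                 step_mV = 0, step_ms = 300) {
  stopifnot(holding_ms > 0, prestep_ms > 0, step_ms > 0)
  p <- tibble::tibble(
    sweep_id = 1L, segment = 1:3,
    v_mV = c(holding_mV, prestep_mV, step_mV),
    dur_ms = c(holding_ms, prestep_ms, step_ms))
  attr(p, "components") <- c("fast", "slow")
  p
}

#' @rdname protocol_inward_step
#' @param from,to,by Test-step voltages, mV.
#' @param dur_ms Test-step duration, ms.
#' @export
protocol_iv <- function(from = -30, to = 60, by = 15, dur_ms = 2500,
                        holding_mV = -80, holding_ms = 50) {
  vs <- seq(from, to, by = by)
  p <- dplyr::bind_rows(lapply(seq_along(vs), function(i)
    tibble::tibble(sweep_id = i, segment = 1:2,
                   v_mV = c(holding_mV, vs[i]),
                   dur_ms = c(holding_ms, dur_ms))))
  attr(p, "components") <- "out"
  p
}

#' @rdname protocol_inward_step
#' @export
protocol_kv_step <- function(from = -40, to = 60, by = 20, dur_ms = 5000,
                             holding_mV = -80, holding_ms = 50) {
  p <- protocol_iv(from = from, to = to, by = by, dur_ms = dur_ms,
                   holding_mV = holding_mV, holding_ms = holding_ms)
  attr(p, "components") <- "out"
  p
}

# Unit-peak alpha-function templates. The fast inward component peaks
# early (t_peak 1.5 ms, well under 10 ms); the slow one uses a 4th-order
# alpha so its foot is negligible at the fast peak and vice versa.
alpha1 <- function(t, tp) ifelse(t > 0, (t / tp) * exp(1 - t / tp), 0)
alpha4 <- function(t, tp) ifelse(t > 0, (t / tp)^4 * exp(4 * (1 - t / tp)), 0)

#' Simulate voltage-clamp sweeps from phenomenological current templates
#'
#' On the protocol's test step the current is the sum of the components the
#' protocol isolates: a brief fast inward transient (peak at 1.5 ms), a
#' slower inward transient (peak at 25 ms) and/or an outward component
#' rising to a plateau `g_out * cm * (V - e_rev_out)`. All amplitudes scale
#' linearly with the membrane capacitance `cm`, so current densities are
#' capacitance-invariant by construction. These are waveform templates
#' only, not membrane kinetics.
#'
#' @param truth An [ephys_truth()].
#' @param protocol A protocol tibble (see [protocol_inward_step()]).
#' @param sample_interval Sampling interval, ms; must be <= 2 ms to resolve
#'   the fast component.
#' @param noise_sd Additive Gaussian current noise, pA.
#' @param seed Integer seed.
#' @return A list with `sweeps` (tibble `sweep_id`, `time_ms`,
#'   `command_mV`, `current_pA`), `truth`, `sample_interval` and
#'   `protocol`.
#' @export
gen_ephys_sweeps <- function(truth, protocol = protocol_inward_step(),
                             sample_interval = 0.2, noise_sd = 2,
                             seed = NULL) {
  stopifnot(inherits(truth, "ephys_truth"))
  if (sample_interval > 2)
    stop("sample_interval > 2 ms cannot resolve the fast inward component",
         call. = FALSE)
  if (any(protocol$dur_ms <= 0))
    stop("protocol durations must be positive", call. = FALSE)
  comps <- attr(protocol, "components")
  with_seed(seed, {
    out <- lapply(split(protocol, protocol$sweep_id), function(pr) {
      pr <- pr[order(pr$segment), ]
      t_end <- cumsum(pr$dur_ms)
      t_on <- c(0, t_end[-length(t_end)])
      t_ms <- seq(0, t_end[length(t_end)] - sample_interval,
                  by = sample_interval)
      seg <- findInterval(t_ms, t_on)
      v <- pr$v_mV[seg]
      # test step = last segment
      k <- nrow(pr)
      ts <- t_ms - t_on[k]
      vstep <- pr$v_mV[k]
      i_pa <- numeric(length(t_ms))
      on <- ts >= 0
      if ("fast" %in% comps)
        i_pa[on] <- i_pa[on] -
          truth$g_fast_in * truth$cm * alpha1(ts[on], 1.5)
      if ("slow" %in% comps)
        i_pa[on] <- i_pa[on] -
          truth$g_slow_in * truth$cm * alpha4(ts[on], 25)
      if ("out" %in% comps && vstep > truth$e_rev_out)
        i_pa[on] <- i_pa[on] +
          truth$g_out * truth$cm * (vstep - truth$e_rev_out) *
          (1 - exp(-ts[on] / 20))
      if (noise_sd > 0) i_pa <- i_pa + stats::rnorm(length(i_pa), 0, noise_sd)
      tibble::tibble(sweep_id = pr$sweep_id[1], time_ms = t_ms,
                     command_mV = v, current_pA = i_pa)
    })
    list(sweeps = dplyr::bind_rows(out), truth = truth,
         sample_interval = sample_interval, protocol = protocol)
  })
}

#' Simulate a stimulus-evoked action potential trace
#'
#' Resting potential until the stimulus, a smooth 2 ms half-cosine
#' upstroke (maximal dV/dt at its midpoint), then linear repolarisation
#' whose slope is set so the trace crosses 80 % repolarisation exactly
#' `apd80_true` ms after the maximal-upstroke-velocity time.
#'
#' @param resting Resting potential, mV.
#' @param peak Peak potential, mV.
#' @param apd80_true Target APD80, ms.
#' @param stim_time Stimulus time, ms.
#' @param duration Trace length, ms.
#' @param sample_interval Sampling interval, ms.
#' @param noise_sd Additive Gaussian noise, mV.
#' @param seed Integer seed.
#' @return A list with `trace` (tibble `time_ms`, `vm_mV`) and `truth`
#'   (`apd80_true`, `resting`, `peak`, `t_upstroke` = time of maximal
#'   dV/dt).
#' @export
gen_ap_trace <- function(resting = -55, peak = 30, apd80_true = 50,
                         stim_time = 50, duration = 300,
                         sample_interval = 0.1, noise_sd = 0.3,
                         seed = NULL) {
  stopifnot(peak > resting, apd80_true > 2)
  with_seed(seed, {
    t_ms <- seq(0, duration, by = sample_interval)
    ampl <- peak - resting
    rise <- 2                       # upstroke duration, ms
    t_up <- stim_time + rise / 2    # maximal dV/dt (midpoint of half-cosine)
    level80 <- peak - 0.8 * ampl
    slope <- (peak - level80) / (apd80_true - rise / 2)  # mV/ms down
    v <- rep(resting, length(t_ms))
    ph <- (t_ms - stim_time) / rise
    up <- ph >= 0 & ph <= 1
    v[up] <- resting + ampl * (1 - cos(pi * ph[up])) / 2
    rep_ <- ph > 1
    v[rep_] <- pmax(resting, peak - slope * (t_ms[rep_] - (stim_time + rise)))
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    list(trace = tibble::tibble(time_ms = t_ms, vm_mV = v),
         truth = list(apd80_true = apd80_true, resting = resting,
                      peak = peak, t_upstroke = t_up,
                      stim_time = stim_time))
  })
}
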