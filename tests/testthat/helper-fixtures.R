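# Fixtures built in code: analytic shapes, reference traces and an
# independent brute-force Mann-Whitney oracle.

disk_mask <- function(r_px, pad = 10) {
  n <- 2 * r_px + 2 * pad
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(r, c) sqrt((r - ctr)^2 + (c - ctr)^2) <= r_px)
}

square_mask <- function(s_px, pad = 10) {
  m <- matrix(FALSE, s_px + 2 * pad, s_px + 2 * pad)
  m[pad + 1:s_px, pad + 1:s_px] <- TRUE
  m
}

# Triadic Koch curve rasterised with one pixel per unit segment
# (level 6: 4^6 segments), as a 1-pixel curve image.
koch_curve_mask <- function(level = 6) {
  ang <- 0
  for (l in seq_len(level)) {
    new <- c()
    for (a in ang) new <- c(new, a, a + 60, a - 60, a)
    ang <- new
  }
  a <- ang * pi / 180
  xs <- cumsum(c(0, cos(a)))
  ys <- cumsum(c(0, sin(a)))
  img <- matrix(FALSE,
                ceiling(max(ys)) - floor(min(ys)) + 3,
                ceiling(max(xs)) - floor(min(xs)) + 3)
  img[cbind(round(ys - min(ys)) + 2L, round(xs - min(xs)) + 2L)] <- TRUE
  img
}

# Noiseless single-exponential transient sampled on a regular grid.
exp_decay_trace <- function(tau, onset_ms = 1000, dt = 20, dur = 6000,
                            baseline = 100, amplitude = 100) {
  t_ms <- seq(0, dur, by = dt)
  v <- baseline + ifelse(t_ms >= onset_ms,
                         amplitude * exp(-(t_ms - onset_ms) / tau), 0)
  fluor_trace(v, dt)
}

# Independent full-enumeration Mann-Whitney oracle: for every labelling of
# the pooled values, U for the first group from the rank-sum definition;
# two-sided p = 2 * min(tails) capped at 1.
mw_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  u_of <- function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  sets <- utils::combn(length(pool), n1, simplify = FALSE)
  us <- vapply(sets, u_of, numeric(1))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= obs + eps), mean(us >= obs - eps)))
  list(u = obs, p = p)
}

# A movie with a pulse marching one pixel per frame along a 1 x npx strip:
# pixel j is bright for `width` frames starting at frame j + lead.
marching_pulse_stack <- function(npx = 10, nf = 30, lead = 3L, width = 3L,
                                 lo = 100, hi = 200, dt = 110, px = 10) {
  fr <- array(lo, dim = c(nf, 1, npx))
  for (j in seq_len(npx)) {
    on <- j + lead
    fr[on:min(nf, on + width - 1L), 1, j] <- hi
  }
  frame_stack(fr, dt, px)
}
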