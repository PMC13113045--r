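#' Frame-censored capture probability
#'
#' A wavefront traversing a cluster in time `t` is captured entirely
#' within a single camera frame when no frame boundary falls inside the
#' traversal window. With the wave start phase uniform over the frame
#' interval, that probability is `p = max(0, 1 - t / delta_t)`.
#'
#' @param t Traversal time, ms (>= 0).
#' @param delta_t Frame acquisition interval, ms (> 0).
#' @return Capture probability in `[0, 1]` (vectorised over `t`).
#' @examples
#' capture_probability(15, 110)   # 0.8636
#' @export
capture_probability <- function(t, delta_t) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  check_positive_scalar(delta_t, "delta_t")
  pmax(0, 1 - t / delta_t)
}

#' Confidence upper bound on the traversal time
#'
#' Observing the single-frame outcome in `k` consecutive recordings at
#' significance level `alpha` implies `p^k >= alpha` is untenable only
#' when `p < alpha^(1/k)`, giving `T <= delta_t * (1 - alpha^(1/k))`.
#' The bound is strictly decreasing in `k`: more consecutive captures pin
#' the traversal time closer to zero.
#'
#' `variant = "alt"` evaluates the `(1 - alpha)^(1/k)` form,
#' `delta_t * (1 - (1 - alpha)^(1/k))`, kept for comparison: it is not
#' consistent with the event `p >= alpha^(1/k)` and collapses toward 0 for
#' small `alpha` (see the methods vignette).
#'
#' @param delta_t Frame interval, ms.
#' @param k Number of consecutive single-frame observations (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param variant `"primary"` (`alpha^(1/k)`) or `"alt"`.
#' @return Upper bound on the traversal time, ms.
#' @examples
#' traversal_bound(110, 19, 0.05)   # 16.05 ms
#' traversal_bound(110, 21, 0.05)   # 14.62 ms
#' @export
traversal_bound <- function(delta_t, k, alpha = 0.05,
                            variant = c("primary", "alt")) {
  variant <- match.arg(variant)
  check_positive_scalar(delta_t, "delta_t")
  if (any(k < 1) || any(k != round(k)))
    stop("`k` must be a positive integer", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  switch(variant,
         primary = delta_t * (1 - alpha^(1 / k)),
         alt = delta_t * (1 - (1 - alpha)^(1 / k)))
}

#' Conduction-velocity lower bound
#'
#' `CV = L / T > L / T_upper`; with `L` in um and `T` in ms the result is
#' in um/ms = mm/s.
#'
#' @param cluster_length Cluster length L, um.
#' @param t_upper Traversal-time upper bound, ms.
#' @return CV lower bound, mm/s.
#' @examples
#' cv_lower_bound(300, 14.6)   # 20.5 mm/s
#' @export
cv_lower_bound <- function(cluster_length, t_upper) {
  check_positive_scalar(cluster_length, "cluster_length")
  check_positive_scalar(t_upper, "t_upper")
  cluster_length / t_upper
}

#' Pooled CV bound from classified propagation events
#'
#' When every event was captured within a single frame, `k` is the event
#' count and the bound applies, with the most conservative choice of
#' cluster length (the minimum across events). Any multi-frame event
#' refutes the premise of the censored bound; it is then refused and
#' direct activation-map gradient estimation ([estimate_cv()]) is
#' recommended instead.
#'
#' @param events A tibble of [classify_event()] rows (all sharing
#'   `delta_t_ms`).
#' @param alpha Significance level.
#' @param variant Bound variant, see [traversal_bound()].
#' @return An object of class `cv_bound`: `delta_t`, `k`, `alpha`,
#'   `p_min = alpha^(1/k)`, `t_upper` (ms), `cluster_length` (um),
#'   `cv_lower` (mm/s), `refused`, `reason`.
#' @export
estimate_from_events <- function(events, alpha = 0.05,
                                 variant = c("primary", "alt")) {
  variant <- match.arg(variant)
  if (nrow(events) < 1L) stop("need >= 1 event", call. = FALSE)
  dts <- unique(events$delta_t_ms)
  if (length(dts) != 1L)
    stop("events mix frame intervals: ", paste(dts, collapse = ", "),
         call. = FALSE)
  if (any(events$outcome == "multi_frame")) {
    res <- list(delta_t = dts, k = NA_integer_, alpha = alpha,
                p_min = NA_real_, t_upper = NA_real_,
                cluster_length = NA_real_, cv_lower = NA_real_,
                variant = variant, refused = TRUE,
                reason = paste0(
                  sum(events$outcome == "multi_frame"),
                  " multi-frame event(s) present; the censored bound does ",
                  "not apply - estimate CV from the activation-map gradient"))
    return(structure(res, class = "cv_bound"))
  }
  k <- nrow(events)
  t_up <- traversal_bound(dts, k, alpha, variant)
  len <- min(events$cluster_length_um)
  structure(list(delta_t = dts, k = k, alpha = alpha,
                 p_min = alpha^(1 / k), t_upper = t_up,
                 cluster_length = len,
                 cv_lower = cv_lower_bound(len, t_up),
                 variant = variant, refused = FALSE, reason = NA_character_),
            class = "cv_bound")
}

#' @rdname estimate_from_events
#' @param delta_t,k,cluster_length Direct construction of a bound without
#'   an event table (`cluster_length` optional).
#' @export
cv_bound <- function(delta_t, k, alpha = 0.05, cluster_length = NULL,
                     variant = c("primary", "alt")) {
  variant <- match.arg(variant)
  t_up <- traversal_bound(delta_t, k, alpha, variant)
  structure(list(delta_t = delta_t, k = as.integer(k), alpha = alpha,
                 p_min = alpha^(1 / k), t_upper = t_up,
                 cluster_length = cluster_length %||% NA_real_,
                 cv_lower = if (!is.null(cluster_length))
                   cv_lower_bound(cluster_length, t_up) else NA_real_,
                 variant = variant, refused = FALSE, reason = NA_character_),
            class = "cv_bound")
}

#' @export
print.cv_bound <- function(x, ...) {
  if (isTRUE(x$refused)) {
    cat("<cv_bound> refused:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<cv_bound> dt = %g ms, k = %d, alpha = %g (%s)\n  T <= %.2f ms%s\n",
    x$delta_t, x$k, x$alpha, x$variant, x$t_upper,
    if (is.finite(x$cv_lower))
      sprintf("; CV > %.1f mm/s (L = %g um)", x$cv_lower, x$cluster_length)
    else ""))
  invisible(x)
}

#' @export
tidy.cv_bound <- function(x, ...) {
  tibble::tibble(
    term = c("p_min", "t_upper_ms", "cv_lower_mm_s"),
    estimate = c(x$p_min, x$t_upper, x$cv_lower))
}

#' @export
glance.cv_bound <- function(x, ...) {
  tibble::tibble(delta_t_ms = x$delta_t, k = x$k, alpha = x$alpha,
                 variant = x$variant, t_upper_ms = x$t_upper,
                 cluster_length_um = x$cluster_length,
                 cv_lower_mm_s = x$cv_lower, refused = isTRUE(x$refused))
}

#' Monte-Carlo oracle for the censored bound
#'
#' Simulates wave start phases uniform in `[0, delta_t)` and returns the
#' fraction of runs in which `k` consecutive beats are all captured within
#' a single frame. At `t_true = traversal_bound(delta_t, k, alpha)` this
#' rate equals `alpha` (the bound is exact, not conservative, at its own
#' boundary).
#'
#' @param t_true True traversal time, ms.
#' @param delta_t Frame interval, ms.
#' @param k Consecutive captures required.
#' @param n_sim Number of simulated runs (>= 1000).
#' @param seed Integer seed.
#' @return Empirical consecutive-capture rate.
#' @export
mc_validate <- function(t_true, delta_t, k, n_sim = 10000, seed = NULL) {
  if (n_sim < 1000) stop("n_sim must be >= 1000", call. = FALSE)
  stopifnot(t_true >= 0, k >= 1)
  with_seed(seed, {
    ph <- matrix(stats::runif(n_sim * k, 0, delta_t), n_sim, k)
    mean(apply(ph + t_true <= delta_t, 1, all))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
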