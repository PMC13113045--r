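#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' U is computed from rank sums with midranks for ties. When both group
#' sizes are at most `exact_limit` the two-sided p value is obtained by
#' full enumeration of all `choose(n1 + n2, n1)` group labelings of the
#' observed values — valid with ties, unlike the classical exact tables.
#' Otherwise a normal approximation with tie correction and continuity
#' correction is used. The two-sided p is `2 * min(lower tail, upper
#' tail)` capped at 1.
#'
#' @param x,y Numeric samples (>= 1 each).
#' @param exact_limit Enumerate exactly when `max(n1, n2) <= exact_limit`.
#' @return A list of class `mw_test`: `statistic` (U for `x`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approximation"`),
#'   `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided   # 0.1
#' @export
mann_whitney <- function(x, y, exact_limit = 8) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))                       # midranks for ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_limit) {
    comb <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[comb], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    lower <- mean(us <= u + eps)
    upper <- mean(us >= u - eps)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sig2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(statistic = u, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_two_sided,
                 method = x$method, n1 = x$n1, n2 = x$n2)
}

#' Gaussian mean +/- SD summary
#'
#' @param values Numeric vector.
#' @return A tibble: `mean`, `sd` (n-1 denominator; `NA` with
#'   `sd_defined = FALSE` when n < 2), `n`.
#' @export
gaussian_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) stop("no values", call. = FALSE)
  tibble::tibble(mean = mean(values),
                 sd = if (n >= 2) stats::sd(values) else NA_real_,
                 n = n, sd_defined = n >= 2)
}
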