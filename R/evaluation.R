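# Method-comparison statistics: sum of squared errors and the Wilcoxon
# signed-rank test (exact by rank-sum enumeration, or normal approximation
# with tie correction).

#' Sum of squared errors
#'
#' @param measured,recovered Equal-length numeric vectors (measured
#'   exposures and exposures recovered by a linearisation method).
#' @return `sum((measured - recovered)^2)`.
#' @export
sse <- function(measured, recovered) {
  if (length(measured) != length(recovered) || length(measured) < 1L) {
    stop("`measured` and `recovered` must be equal-length, non-empty",
         call. = FALSE)
  }
  sum((measured - recovered)^2)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided Wilcoxon signed-rank test.  Zero differences are
#' dropped (Wilcoxon's original treatment) and their count reported;
#' absolute differences are ranked with midranks for ties.  The statistic
#' is `W = min(W+, W-)`.  In `"exact"` mode the p-value is
#' `P(min(W+, W-) <= W_obs)` under the exact null distribution of signed
#' rank sums (computed by convolution over the doubled ranks, so midranks
#' are handled exactly); `"normal_approx"` uses the tie-corrected normal
#' approximation with continuity correction.  `"auto"` switches from exact
#' to approximate above n = 12 pairs to bound runtime.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return A list with `W`, `p_value`, `n_pairs` (non-zero pairs),
#'   `n_zero_diffs` and `mode` (the mode actually used).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 mode = c("auto", "exact",
                                          "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero: the signed-rank test is degenerate",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  if (mode == "auto") mode <- if (n <= 12L) "exact" else "normal_approx"
  if (mode == "exact") {
    p <- .wsr_exact_p(r, W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
  }
  list(W = W, p_value = p, n_pairs = n, n_zero_diffs = n_zero, mode = mode)
}

# exact null distribution of W+ over doubled ranks (integers even with
# midranks), by polynomial convolution; returns P(min(W+, W-) <= W_obs)
.wsr_exact_p <- function(r, W_obs) {
  r2 <- round(2 * r)
  tot <- sum(r2)
  counts <- c(1, rep(0, tot))  # counts[s + 1] = # assignments with 2*W+ = s
  for (rk in r2) {
    shifted <- c(rep(0, rk), counts[seq_len(tot + 1 - rk)])
    counts <- counts + shifted
  }
  w2 <- round(2 * W_obs)
  s <- 0:tot
  lower <- sum(counts[s <= w2])
  upper <- sum(counts[s >= tot - w2])
  overlap <- if (w2 * 2 >= tot) sum(counts[s <= w2 & s >= tot - w2]) else 0
  (lower + upper - overlap) / 2^length(r)
}

#' Compare two linearisation methods on the same measurements
#'
#' Computes the SSE of each method against the measured exposures and the
#' two-sided Wilcoxon signed-rank test between the two sets of recovered
#' exposures.
#'
#' @param measured Measured exposures.
#' @param recovered_biexp,recovered_bezier Exposures recovered by each
#'   method, aligned with `measured`.
#' @param mode Passed to [wilcoxon_signed_rank()].
#' @return An object of class `comparison_result` with fields `sse_biexp`,
#'   `sse_bezier`, `wilcoxon_W`, `p_value`, `n_pairs`, `n_zero_diffs`.
#' @export
compare_linearisations <- function(measured, recovered_biexp,
                                   recovered_bezier, mode = "auto") {
  s1 <- sse(measured, recovered_biexp)
  s2 <- sse(measured, recovered_bezier)
  w <- wilcoxon_signed_rank(recovered_biexp, recovered_bezier, mode = mode)
  structure(list(sse_biexp = s1, sse_bezier = s2, wilcoxon_W = w$W,
                 p_value = w$p_value, n_pairs = w$n_pairs,
                 n_zero_diffs = w$n_zero_diffs),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> SSE biexp=%.4g, SSE bezier=%.4g; W=%g, p=%.3f (n=%d, %d zero diffs)\n",
    x$sse_biexp, x$sse_bezier, x$wilcoxon_W, x$p_value, x$n_pairs,
    x$n_zero_diffs))
  invisible(x)
}
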