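#' Paired Wilcoxon signed-rank test
#'
#' Differences `d = y - x`; zero differences are dropped (`N` = number of
#' nonzero pairs), absolute differences are ranked with average ranks for
#' ties, and `W` is the sum of the ranks of the positive differences. The
#' one-sided p-value is exact (full distribution of the positive-rank sum
#' over all `2^N` sign assignments, computed by convolution) when `N <= 20`
#' and there are no ties; otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Equal-length paired samples.
#' @param alternative `"greater"` (y tends to exceed x), `"less"`, or
#'   `"two.sided"`.
#' @return An `sq_wilcoxon`: `W`, `N`, `p`, `alternative`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(3, 5, 7), "greater")  # W = 6, p = 0.125
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 1) {
    stop_bad_arg("`x` and `y` must be paired samples of equal length >= 1")
  }
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_bad_arg("no nonzero pairs: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 20 && !ties) {
    method <- "exact"
    # P(W* <= w) from the exact null distribution of the positive-rank sum
    cdf <- signed_rank_cdf(n)
    p_le <- cdf[W + 1]
    p_ge <- if (W == 0) 1 else 1 - cdf[W]
  } else {
    method <- "normal-approx-with-tie-correction"
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    sigma <- sqrt(sigma2)
    p_ge <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((W - mu + 0.5) / sigma)
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(W = W, N = n, p = p, alternative = alternative,
                 method = method),
            class = "sq_wilcoxon")
}

# Exact CDF of the positive-rank-sum statistic for integer ranks 1..n:
# cdf[w + 1] = P(W <= w). Dynamic-programming convolution over rank
# inclusion, equivalent to enumerating all 2^n sign assignments.
signed_rank_cdf <- function(n) {
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  cumsum(counts) / 2^n
}

#' @export
print.sq_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g (N = %d), one-tailed p %s (%s, %s)\n",
              x$W, x$N,
              if (x$p < 1e-4) sprintf("< 0.0001") else sprintf("= %.4f", x$p),
              x$alternative, x$method))
  invisible(x)
}

#' @rdname wilcoxon_signed_rank
#' @param x An `sq_wilcoxon` (for `tidy`).
#' @param ... Unused.
#' @export
tidy.sq_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$W, n = x$N, p.value = x$p,
                 alternative = x$alternative, method = x$method)
}
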