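#' Wilcoxon signed-rank test with Z and r effect size
#'
#' Paired-sample rank test. Zero differences are discarded (Wilcoxon
#' convention); absolute differences are midranked. The Z statistic uses
#' the tie-corrected normal approximation
#' `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' (no continuity correction), with `W` the positive-rank sum. For
#' `n <= exact_limit` non-zero differences the p-value is exact, computed
#' from the full null distribution of `W` under independent sign flips
#' (generating-function convolution, valid under ties); otherwise the
#' normal approximation is used. The effect size is `r = Z / sqrt(N)` with
#' `N` the number of input pairs.
#'
#' @param x,y Paired samples, or differences in `x` with `y = NULL`.
#' @param exact_limit Largest `n` for which the exact null distribution is
#'   enumerated.
#' @return A `stat_result` with statistic `"z"` (the tie-corrected Z; its
#'   sign follows `x - y`), `n`, two-sided `p`, and `r`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- if (n <= exact_limit) {
    signed_rank_exact_p(r, w_pos)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  stat_result(
    statistic = "z", value = z, n = n_pairs, p = min(p, 1),
    effect_size = z / sqrt(n_pairs), effect_size_type = "r",
    effect_size_formula = "r = Z/sqrt(N)"
  )
}

# Exact two-sided p for the signed-rank sum: distribution of W+ over the
# 2^n equiprobable sign assignments, via convolution over doubled midranks
# (doubling makes tied midranks integral).
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- (f + shifted) / 2
  }
  w2 <- as.integer(round(2 * w_obs))
  lower <- sum(f[seq_len(w2 + 1L)])
  upper <- sum(f[(w2 + 1L):(total + 1L)])
  min(2 * min(lower, upper), 1)
}

#' Mann-Whitney U test with Z and r effect size
#'
#' Two-sample rank test. `U` is reported for the first sample. The Z
#' statistic uses the tie-corrected normal approximation (no continuity
#' correction); for `n_total <= exact_limit` the p-value is exact,
#' enumerated over all group labelings via a subset-sum count (valid under
#' ties). Effect size is `r = Z / sqrt(N_total)`.
#'
#' @param x,y The two samples.
#' @param exact_limit Largest total sample size for exact enumeration.
#' @return A `stat_result` with statistic `"z"`, the `U` value in
#'   `$u`, `n`, two-sided `p`, and `r`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 25L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty", call. = FALSE)
  n <- nx + ny
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  u <- rx - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {   # all observations identical
    z <- 0
    p <- 1
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p <- if (n <= exact_limit) {
      rank_sum_exact_p(r, nx, rx)
    } else {
      2 * stats::pnorm(-abs(z))
    }
  }
  res <- stat_result(
    statistic = "z", value = z, n = n, p = min(p, 1),
    effect_size = z / sqrt(n), effect_size_type = "r",
    effect_size_formula = "r = Z/sqrt(N_total)"
  )
  res$u <- u
  res
}

# Exact two-sided p for the first-group rank sum over all C(n, nx)
# labelings: dynamic program counting k-subsets of the (doubled) ranks by
# their sum.
rank_sum_exact_p <- function(ranks, nx, rx_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # counts[k+1, s+1] = number of k-subsets with doubled-rank sum s
  counts <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (ri in r2) {
    for (k in nx:1) {
      shifted <- c(numeric(ri), counts[k, seq_len(total + 1L - ri)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[nx + 1L, ]
  dist <- dist / sum(dist)
  s2 <- as.integer(round(2 * rx_obs))
  lower <- sum(dist[seq_len(s2 + 1L)])
  upper <- sum(dist[(s2 + 1L):(total + 1L)])
  min(2 * min(lower, upper), 1)
}

#' Pearson correlation screened by Cook's distance
#'
#' Fits the simple regression `score ~ measure`, removes points whose
#' Cook's distance exceeds `4 / N` (the standard leverage rule), and
#' reports the Pearson correlation on the retained points.
#'
#' @param measure,score Numeric vectors.
#' @return `list(test, retained, removed)` with a `stat_result`
#'   (statistic `"r_pearson"`) and index bookkeeping.
#' @export
cooks_filtered_correlation <- function(measure, score) {
  stopifnot(length(measure) == length(score))
  n <- length(measure)
  fit <- stats::lm(score ~ measure)
  cd <- stats::cooks.distance(fit)
  keep <- cd <= 4 / n
  if (!any(keep)) stop("all points removed by the Cook's rule", call. = FALSE)
  ct <- stats::cor.test(measure[keep], score[keep], method = "pearson")
  test <- stat_result(
    statistic = "r_pearson", value = unname(ct$estimate),
    df = unname(ct$parameter), n = sum(keep), p = ct$p.value,
    effect_size = unname(ct$estimate), effect_size_type = "r",
    effect_size_formula = "Pearson r on Cook's-retained points"
  )
  list(test = test, retained = which(keep), removed = which(!keep))
}
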