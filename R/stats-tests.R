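# Core statistical tests. The two-sided conventions here are load-bearing
# (enrichment directionality depends on them), so they are implemented
# explicitly rather than hidden behind wrapper defaults.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by the "probability at most that of the observed table"
#' rule: the sum of hypergeometric probabilities, over tables with the same
#' margins, that do not exceed the observed table's probability (a relative
#' tie tolerance of 1e-7 absorbs floating-point noise, matching standard
#' implementations). The conditional maximum-likelihood odds ratio is
#' reported.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @param odds_ratio Estimate the conditional odds ratio? Root-finding is
#'   the expensive part; set `FALSE` in bulk p-value sweeps.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `degenerate` (`TRUE`
#'   when a margin is zero, in which case `p = 1` and the odds ratio is
#'   undefined).
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab, odds_ratio = TRUE) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c2   # column-1 margin (successes)
  n <- b + d    # column-2 margin
  k <- a + b    # row-1 margin
  if (m == 0 || n == 0 || k == 0 || c2 + d == 0) {
    return(tibble(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- if (odds_ratio) cond_mle_or(a, m, n, k) else NA_real_
  tibble(odds_ratio = or, p_value = p, degenerate = FALSE)
}

# Conditional MLE of the odds ratio in the noncentral hypergeometric model.
cond_mle_or <- function(x, m, n, k) {
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  logdc <- stats::dhyper(support, m, n, k, log = TRUE)
  mean_x <- function(log_or) {
    d <- logdc + support * log_or
    d <- exp(d - max(d))
    sum(support * d) / sum(d)
  }
  exp(stats::uniroot(function(log_or) mean_x(log_or) - x, c(-50, 50),
                     tol = 1e-10)$root)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed with midranks for ties. When both samples have at most 20
#' observations and there are no ties, the p-value is exact (Wilcoxon
#' rank-sum distribution); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. Samples that
#' are entirely tied with each other give p = 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return A one-row tibble: `u` (U statistic for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && min(nx, ny) <= 20) {
    # exact: P(U <= u) and P(U >= u) from the Wilcoxon rank-sum distribution
    p <- 2 * min(stats::pwilcox(u, nx, ny),
                 stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE))
    return(tibble(u = u, p_value = min(1, p), method = "exact",
                  n_x = nx, n_y = ny))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties)
  sig2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) {
    return(tibble(u = u, p_value = 1, method = "normal", n_x = nx, n_y = ny))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  tibble(u = u, p_value = p, method = "normal", n_x = nx, n_y = ny)
}
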