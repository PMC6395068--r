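# Shared statistical primitives: BH step-up FDR, exact overlap tests on a
# 2x2 margin, the Pearson correlation test, normal-theory regression bands,
# and pooled group summaries. These are deliberately authored here (not
# delegated to p.adjust/fisher.test) so the tests can check them against
# those functions and against brute-force enumeration as independent oracles.

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p values to q values with the standard step-up rule
#' `q_(i) = min_(j >= i) p_(j) * m / j`, ties handled by maximal rank,
#' clipped to `[0, 1]`, returned in input order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return numeric vector of q values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
  q
}

#' A 2x2 overlap margin
#'
#' `k` genes shared between a query of size `n` and a set of size `K`,
#' inside a universe of `N` symbols. Validates the hypergeometric support
#' constraints.
#'
#' @param k,K,n,N overlap count, set size, query size, universe size.
#' @return list of class `Overlap2x2`.
#' @export
overlap2x2 <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
  if (k < 0 || k > min(K, n)) stop("k must lie in [0, min(K, n)]", call. = FALSE)
  if (k < n + K - N) stop("k below the support minimum n+K-N", call. = FALSE)
  structure(list(k = k, K = K, n = n, N = N), class = "Overlap2x2")
}

#' Hypergeometric upper-tail overlap probability
#'
#' Exact `P(X >= k)` where X counts members of a size-`K` set in a size-`n`
#' draw without replacement from a universe of `N`. This is the enrichment
#' p value used by MSigDB-style overlap tools.
#'
#' @param t an [overlap2x2()] table.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(t) {
  stopifnot(inherits(t, "Overlap2x2"))
  if (t$k == 0L) return(1)
  p <- stats::phyper(t$k - 1L, t$K, t$N - t$K, t$n, lower.tail = FALSE)
  min(max(p, 0), 1)
}

#' One-sided Fisher's exact test for list overlap
#'
#' Enrichment-direction exact test on the 2x2 table
#' `(k, n-k; K-k, N-K-n+k)`. The one-sided p equals the hypergeometric
#' upper tail at `k` (identical tail definitions); the odds ratio reported
#' is the sample (cross-product) odds ratio, `Inf` when a discordant cell
#' is empty. A degenerate table with a zero margin returns p = 1 with a
#' warning rather than an error so permutation loops survive it.
#'
#' @param t an [overlap2x2()] table.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_overlap <- function(t) {
  stopifnot(inherits(t, "Overlap2x2"))
  a <- t$k; b <- t$n - t$k; c <- t$K - t$k; d <- t$N - t$K - t$n + t$k
  if (t$n == 0L || t$K == 0L || t$n == t$N || t$K == t$N) {
    warning("degenerate 2x2 margin; returning p = 1", call. = FALSE)
    return(list(odds_ratio = NaN, p = 1))
  }
  or <- if (b == 0L || c == 0L) {
    if (a == 0L || d == 0L) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = hypergeom_upper_tail(t))
}

#' Pearson correlation with the exact t test
#'
#' Computes r and the two-sided p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom —
#' the same test `cor.test()` performs.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`, `df`, `statistic`.
#' @export
pearson_correlation_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0)
    stop("zero variance in x or y", call. = FALSE)
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (abs(r) == 1) {
    stat <- Inf * sign(r); p <- 0
  } else {
    stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  list(r = r, p = p, n = n, df = df, statistic = stat)
}

#' Least-squares line with confidence and prediction bands
#'
#' Simple linear regression of y on x with the normal-theory pointwise
#' confidence band for the mean response and prediction band for a new
#' observation, both at the requested level, evaluated at `at` (default:
#' the observed x, sorted).
#'
#' @param x,y numeric vectors, length >= 3.
#' @param level band coverage, default 0.95.
#' @param at evaluation points for the bands.
#' @return list with `slope`, `intercept`, `sigma`, `df`, and a data.frame
#'   `bands` with columns x, fit, ci_lo, ci_hi, pi_lo, pi_hi.
#' @export
ols_line_with_intervals <- function(x, y, level = 0.95, at = sort(x)) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("zero variance in x", call. = FALSE)
  slope <- sum((x - xbar) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * xbar
  resid <- y - intercept - slope * x
  df <- n - 2L
  sigma <- sqrt(sum(resid^2) / df)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  fit <- intercept + slope * at
  se_mean <- sigma * sqrt(1 / n + (at - xbar)^2 / sxx)
  se_pred <- sigma * sqrt(1 + 1 / n + (at - xbar)^2 / sxx)
  bands <- data.frame(x = at, fit = fit,
                      ci_lo = fit - tcrit * se_mean,
                      ci_hi = fit + tcrit * se_mean,
                      pi_lo = fit - tcrit * se_pred,
                      pi_hi = fit + tcrit * se_pred)
  list(slope = slope, intercept = intercept, sigma = sigma, df = df,
       level = level, bands = bands)
}

#' Sample-size-weighted pooled mean
#'
#' `sum(n_i * m_i) / sum(n_i)` — the mean obtained by pooling groups with
#' known per-group means and sizes (e.g. pooling cotinine concentrations
#' across sex and genotype within one exposure duration).
#'
#' @param group_means numeric vector of group means.
#' @param group_ns integer vector of group sizes, same length.
#' @return the pooled mean.
#' @export
pooled_weighted_mean <- function(group_means, group_ns) {
  if (length(group_means) == 0L) stop("empty input", call. = FALSE)
  if (length(group_means) != length(group_ns))
    stop("means and ns must have equal length", call. = FALSE)
  if (any(group_ns < 1)) stop("group sizes must be >= 1", call. = FALSE)
  sum(group_ns * group_means) / sum(group_ns)
}

# round-half-up to whole numbers (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
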