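#' Clopper-Pearson exact binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles: the lower bound is the
#' alpha/2 quantile of Beta(x, n - x + 1) (exactly 0 when x = 0) and the
#' upper bound the 1 - alpha/2 quantile of Beta(x + 1, n - x) (exactly 1
#' when x = n). Coverage is at least the nominal level, at the price of
#' conservatism.
#'
#' @param x Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lo, hi)` of fractions.
#' @export
#' @examples
#' round(100 * clopper_pearson(64, 2339), 2)  # 2.11 3.48
clopper_pearson <- function(x, n, level = 0.95) {
  .check_binom(x, n, level)
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

#' Wilson score binomial confidence interval
#'
#' Score interval with z the standard-normal 1 - alpha/2 quantile: center
#' (p + z^2/2n) / (1 + z^2/n), half-width
#' z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n), clipped to [0, 1]. Narrower
#' than Clopper-Pearson with near-nominal coverage.
#'
#' @inheritParams clopper_pearson
#' @return Numeric vector `c(lo, hi)` of fractions.
#' @export
#' @examples
#' round(100 * wilson(64, 2339), 2)  # 2.15 3.48
wilson <- function(x, n, level = 0.95) {
  .check_binom(x, n, level)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at x = 0 (x = n) the bound is exactly 0 (1); avoid rounding residue
  lo <- if (x == 0) 0 else max(0, center - hw)
  hi <- if (x == n) 1 else min(1, center + hw)
  c(lo = lo, hi = hi)
}

.check_binom <- function(x, n, level) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop("need integers 0 <= x <= n with n >= 1")
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
}

#' Pearson chi-squared test of independence
#'
#' The Pearson statistic sum (O - E)^2 / E over an R x C contingency table,
#' without continuity correction, with expected counts from the row/column
#' margins. Degenerate all-zero rows or columns are dropped (with a
#' warning) before computing, reducing the degrees of freedom
#' (R - 1)(C - 1) accordingly; the p-value is the upper chi-squared tail.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2 before or
#'   after dropping empty margins.
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' pearson_chi2(rbind(c(2275, 64, 0), c(2114, 217, 8)))$statistic  # 97.212
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must contain non-negative integer counts")
  }
  if (sum(m) <= 0) stop("table has zero grand total")
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s); degrees of freedom reduced")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 non-degenerate rows and columns")
  }
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

# log null probability of a contingency table given fixed margins
# (multivariate hypergeometric)
.log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Fisher exact test (2 x 2 exact, R x C Monte Carlo)
#'
#' For a 2 x 2 table the two-sided p-value is computed by full enumeration
#' of the hypergeometric support with fixed margins: the sum of
#' probabilities of all tables no more probable than the observed one
#' (with a small relative tolerance against floating-point ties, as is
#' conventional). Larger tables use Monte Carlo over margin-preserving
#' tables drawn with [stats::r2dtable()], with p = (1 + #{as or less
#' probable}) / (B + 1) and its binomial standard error reported. A table
#' with a zero row or column margin has p = 1.
#'
#' @param table Matrix of non-negative integer counts.
#' @param mc_draws Number of Monte Carlo tables for R x C inputs.
#' @param seed Optional integer seed for the Monte Carlo draw (local; does
#'   not disturb the caller's RNG state).
#' @return List `p_value`, `method`, and for Monte Carlo also `se`.
#' @export
fisher_exact <- function(table, mc_draws = 10000L, seed = NULL) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must contain non-negative integer counts")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, method = "degenerate-margin"))
  }
  if (nrow(m) == 2 && ncol(m) == 2) {
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
    support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- stats::dhyper(support, rs[1], rs[2], cs[1])
    p_obs <- stats::dhyper(m[1, 1], rs[1], rs[2], cs[1])
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p_value = min(1, p), method = "exact"))
  }
  lp_obs <- .log_table_prob(m)
  draw <- function() {
    sims <- stats::r2dtable(mc_draws, rowSums(m), colSums(m))
    vapply(sims, .log_table_prob, numeric(1))
  }
  lps <- if (is.null(seed)) draw() else withr_local_seed(seed, draw())
  hits <- sum(lps <= lp_obs + 1e-7)
  p <- (1 + hits) / (mc_draws + 1)
  list(p_value = p, method = "monte-carlo",
       se = sqrt(p * (1 - p) / mc_draws))
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
withr_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Summarize a comparison into an outcome table with confidence intervals
#'
#' For each three-tier outcome: count, percentage of pairs, and 95%
#' Clopper-Pearson and Wilson intervals (as percentages). Percentages and
#' bounds are returned at full precision; use `digits` when printing.
#'
#' @param counts Named integer vector with entries `cannot_exclude`,
#'   `inconclusive`, `exclude` (e.g. `$outcome_counts` from
#'   [compare_all()]), or a `comparison_table`.
#' @param level Confidence level.
#' @return Data frame with one row per outcome: `outcome`, `count`,
#'   `percent`, `cp_lo`, `cp_hi`, `wilson_lo`, `wilson_hi` (all percentage
#'   scale), plus attribute `n_pairs`.
#' @export
outcome_table <- function(counts, level = 0.95) {
  if (inherits(counts, "comparison_table")) counts <- counts$outcome_counts
  lev <- c("cannot_exclude", "inconclusive", "exclude")
  if (!all(lev %in% names(counts))) {
    stop("counts must be named cannot_exclude/inconclusive/exclude")
  }
  counts <- counts[lev]
  n <- sum(counts)
  if (n < 1) stop("empty outcome table")
  rows <- lapply(lev, function(o) {
    x <- counts[[o]]
    cp <- clopper_pearson(x, n, level)
    wi <- wilson(x, n, level)
    data.frame(outcome = o, count = x, percent = 100 * x / n,
               cp_lo = 100 * cp[["lo"]], cp_hi = 100 * cp[["hi"]],
               wilson_lo = 100 * wi[["lo"]], wilson_hi = 100 * wi[["hi"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_pairs") <- n
  out
}
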