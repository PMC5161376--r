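## Descriptive and nonparametric statistics: summaries, Spearman rank
## correlation, rank-based group tests, percentage agreement with Cohen's
## kappa, and the design-stage sample-size computation.

#' Descriptive summary of a numeric series
#'
#' Mean/SD plus the quantiles used by the box-whisker displays (quartiles,
#' 5th/95th percentiles, extremes).  Quantiles use linear interpolation
#' between order statistics (R type 7), the documented convention of the
#' package.  Missing values are excluded (per-outcome exclusion).
#'
#' @param x numeric vector.
#' @return one-row `data.frame`: `n`, `mean`, `sd`, `min`, `p5`, `q1`,
#'   `median`, `q3`, `p95`, `max` (all `NA` when `n = 0`).
#' @export
describe <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_, min = NA_real_,
                      p5 = NA_real_, q1 = NA_real_, median = NA_real_,
                      q3 = NA_real_, p95 = NA_real_, max = NA_real_))
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  data.frame(n = length(x), mean = mean(x),
             sd = if (length(x) > 1) sd(x) else 0,
             min = min(x), p5 = q[1], q1 = q[2], median = q[3], q3 = q[4],
             p95 = q[5], max = max(x))
}

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.  Pairs with any missing value
#' are dropped; degenerate (constant) series give a missing estimate.
#'
#' @param x,y paired numeric vectors.
#' @return `data.frame` with `rho`, `n`, `p`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(data.frame(rho = NA_real_, n = n, p = NA_real_))
  if (var(x) == 0 || var(y) == 0) {
    warning("constant series: Spearman correlation undefined")
    return(data.frame(rho = NA_real_, n = n, p = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  data.frame(rho = rho, n = n, p = p)
}

#' Rank-based and chi-square group comparisons
#'
#' Dispatch to the tests used for subgroup comparison: Wilcoxon rank-sum for
#' a continuous outcome over two groups, Wilcoxon signed-rank for paired
#' series (zero differences dropped, mid-ranks for ties), Pearson chi-square
#' for categorical outcomes.
#'
#' @param values numeric outcome (or factor for `type = "chisq"`).
#' @param groups two-level factor (`ranksum`, `chisq`), or the second paired
#'   series (`signedrank`).
#' @param type test type.
#' @return `data.frame` with `statistic`, `p`, `n`, `test`.
#' @export
group_tests <- function(values, groups,
                        type = c("ranksum", "signedrank", "chisq")) {
  type <- match.arg(type)
  if (type == "ranksum") {
    g <- droplevels(factor(groups))
    ok <- !is.na(values) & !is.na(g)
    if (nlevels(droplevels(g[ok])) != 2 || !sum(ok))
      return(data.frame(statistic = NA_real_, p = NA_real_, n = sum(ok),
                        test = type))
    wt <- suppressWarnings(wilcox.test(values[ok] ~ droplevels(g[ok]),
                                       correct = TRUE))
    data.frame(statistic = unname(wt$statistic), p = wt$p.value, n = sum(ok),
               test = type)
  } else if (type == "signedrank") {
    ok <- !is.na(values) & !is.na(groups)
    if (sum(ok) < 1 || all(values[ok] == groups[ok]))
      return(data.frame(statistic = NA_real_, p = NA_real_, n = sum(ok),
                        test = type))
    wt <- suppressWarnings(wilcox.test(values[ok], as.numeric(groups[ok]),
                                       paired = TRUE, correct = TRUE))
    data.frame(statistic = unname(wt$statistic), p = wt$p.value, n = sum(ok),
               test = type)
  } else {
    ok <- !is.na(values) & !is.na(groups)
    tab <- table(droplevels(factor(values[ok])), droplevels(factor(groups[ok])))
    if (any(dim(tab) < 2))
      return(data.frame(statistic = NA_real_, p = NA_real_, n = sum(ok),
                        test = type))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(statistic = unname(ct$statistic), p = ct$p.value, n = sum(ok),
               test = type)
  }
}

#' Percentage agreement and Cohen's kappa
#'
#' Observed agreement between two categorical series and chance-corrected
#' agreement `kappa = (p_o - p_e) / (1 - p_e)`, with expected agreement
#' `p_e` from the product of the marginal distributions.  The p-value tests
#' `kappa = 0` with the large-sample standard error under independence
#' (Fleiss).  When both raters use a single category, agreement is 100% and
#' kappa is undefined (logged).
#'
#' @param a,b categorical vectors of equal length; pairs with missing values
#'   are dropped.
#' @return `data.frame` with `percent_agreement`, `kappa`, `n`, `p`.
#' @export
agreement <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- factor(a[ok]); b <- factor(b[ok])
  lev <- union(levels(a), levels(b))
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  n <- length(a)
  if (!n) return(data.frame(percent_agreement = NA_real_, kappa = NA_real_,
                            n = 0L, p = NA_real_))
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pi_ <- rowSums(tab); pj <- colSums(tab)
  pe <- sum(pi_ * pj)
  if (pe >= 1) {
    warning("single category used by both raters: kappa undefined")
    return(data.frame(percent_agreement = 100 * po, kappa = NA_real_, n = n,
                      p = NA_real_))
  }
  kap <- (po - pe) / (1 - pe)
  # H0 variance (Fleiss, Levin & Paik)
  var0 <- (pe + pe^2 - sum(pi_ * pj * (pi_ + pj))) / (n * (1 - pe)^2)
  p <- if (var0 > 0) 2 * pnorm(-abs(kap / sqrt(var0))) else NA_real_
  data.frame(percent_agreement = 100 * po, kappa = kap, n = n, p = p)
}

#' Design-stage sample size for a two-group cost comparison
#'
#' Normal-approximation two-sample size with unequal variances
#' (`sigma^2` in the reference group, `sigma^2 * variance_ratio` in the
#' other), inflated for anticipated missing responses and rounded up:
#' `n = (z_{1-alpha/2} + z_{power})^2 * sigma^2 * (1 + variance_ratio /
#' allocation) / delta^2 / (1 - missing_rate)`.
#'
#' @param delta detectable difference (> 0), cost units.
#' @param sd_active SD in the reference (active-disease) group.
#' @param variance_ratio ratio of the other group's variance to the
#'   reference variance (0.5: remission variance halved).
#' @param power,alpha design power and two-sided significance level.
#' @param missing_rate anticipated fraction of missing responses.
#' @param allocation recruitment ratio n_other / n_reference (1 = equal).
#' @return integer sample size per (reference) group.
#' @export
required_sample_size <- function(delta, sd_active, variance_ratio = 0.5,
                                 power = 0.8, alpha = 0.05,
                                 missing_rate = 0.1, allocation = 1) {
  if (delta <= 0 || sd_active <= 0) stop("delta and sd_active must be positive")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  n <- z^2 * sd_active^2 * (1 + variance_ratio / allocation) / delta^2
  as.integer(ceiling(n / (1 - missing_rate)))
}
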