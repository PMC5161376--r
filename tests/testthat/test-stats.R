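# descriptives, rank statistics, agreement, sample size

test_that("describe follows the linear-interpolation quantile convention", {
  d <- describe(1:100)
  expect_equal(d$median, 50.5)
  expect_equal(d$q1, 25.75)
  expect_equal(d$q3, 75.25)
  expect_equal(d$p5, quantile(1:100, 0.05, names = FALSE))
  expect_equal(d$n, 100L)
  # ordering invariant over random draws
  set.seed(12)
  for (i in 1:20) {
    x <- rgamma(sample(3:50, 1), shape = 0.7)
    dd <- describe(x)
    v <- unlist(dd[c("min", "p5", "q1", "median", "q3", "p95", "max")])
    expect_true(all(diff(v) >= -1e-12))
  }
  const <- describe(rep(3.5, 8))
  expect_equal(const$sd, 0)
  expect_true(all(unlist(const[c("min", "q1", "median", "q3", "max")]) == 3.5))
  expect_equal(describe(numeric(0))$n, 0L)
  expect_true(is.na(describe(c(NA, NA))$mean))
})

test_that("spearman_rho equals the reference implementation, ties included", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + rpois(n, 3) - sample(0:4, n, replace = TRUE)
    got <- spearman_rho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  # large-sample p agrees with the t approximation used by cor.test
  x <- rnorm(200); y <- x + rnorm(200)
  expect_equal(spearman_rho(x, y)$p,
               suppressWarnings(cor.test(x, y, method = "spearman",
                                         exact = FALSE)$p.value),
               tolerance = 1e-6)
  expect_warning(r <- spearman_rho(rep(1, 10), 1:10), "constant")
  expect_true(is.na(r$rho))
  expect_true(is.na(spearman_rho(1:2, 2:1)$rho))
})

test_that("rank-sum p matches exact enumeration on small tie-free fixtures", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(6:8, 1)
    x <- sample(seq_len(50), n)   # distinct values, no ties
    g <- factor(rep(c("a", "b"), c(3, n - 3)))
    got <- group_tests(x, g, type = "ranksum")
    expect_equal(got$p, oracle_ranksum_p(x, g), tolerance = 1e-12)
  }
  # identical groups are not significant
  same <- group_tests(c(1:6, 1:6), factor(rep(c("a", "b"), each = 6)))
  expect_gt(same$p, 0.9)
})

test_that("signed-rank and chi-square dispatches behave", {
  set.seed(4)
  x <- rnorm(50); y <- x + 0.8 + rnorm(50, sd = 0.2)
  sr <- group_tests(x, y, type = "signedrank")
  expect_lt(sr$p, 1e-6)
  expect_true(is.na(group_tests(x, x, type = "signedrank")$p))
  tab_val <- rep(c("yes", "no"), c(30, 70))
  tab_grp <- rep(c("g1", "g2"), 50)
  ct <- group_tests(tab_val, tab_grp, type = "chisq")
  ref <- suppressWarnings(chisq.test(table(tab_val, tab_grp),
                                     correct = FALSE))
  expect_equal(ct$statistic, unname(ref$statistic))
  expect_true(is.na(group_tests(numeric(0), factor(levels = c("a", "b")))$p))
})

test_that("agreement and kappa match hand computation", {
  a <- rep(c("act", "act", "rem", "rem"), c(40, 10, 15, 35))
  b <- rep(c("act", "rem", "act", "rem"), c(40, 10, 15, 35))
  got <- agreement(a, b)
  tab <- table(factor(a), factor(b))
  expect_equal(got$kappa, oracle_kappa(tab), tolerance = 1e-12)
  expect_equal(got$percent_agreement, 75)
  perfect <- agreement(c("x", "y", "x"), c("x", "y", "x"))
  expect_equal(perfect$percent_agreement, 100)
  expect_equal(perfect$kappa, 1)
  expect_warning(deg <- agreement(rep("x", 5), rep("x", 5)), "undefined")
  expect_equal(deg$percent_agreement, 100)
  expect_true(is.na(deg$kappa))
  # missing pairs dropped
  expect_equal(agreement(c("x", NA, "y"), c("x", "y", "y"))$n, 2L)
})

test_that("sample size reduces to the textbook formula and scales as 1/delta^2", {
  # equal variances, no missing inflation: classic two-sample formula
  n_eq <- required_sample_size(200, 450, variance_ratio = 1,
                               missing_rate = 0)
  manual <- ceiling((qnorm(0.975) + qnorm(0.8))^2 * 2 * 450^2 / 200^2)
  expect_equal(n_eq, as.integer(manual))
  # halving delta quadruples n (before rounding)
  n1 <- required_sample_size(200, 450)
  n2 <- required_sample_size(100, 450)
  expect_equal(n2 / n1, 4, tolerance = 0.02)
  # monotone decreasing in delta, down to the minimum for huge effects
  deltas <- c(50, 100, 200, 400, 1e6)
  ns <- vapply(deltas, required_sample_size, integer(1), sd_active = 450)
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[length(ns)], 1L)
  # missing-response inflation
  expect_equal(required_sample_size(200, 450, missing_rate = 0.1),
               as.integer(ceiling(
                 (qnorm(0.975) + qnorm(0.8))^2 * 1.5 * 450^2 / 200^2 / 0.9)))
  expect_error(required_sample_size(-1, 450), "positive")
  expect_error(required_sample_size(200, 450, power = 1.2), "0, 1")
})
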