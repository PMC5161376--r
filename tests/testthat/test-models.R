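# fractional logit and two-part cost models

test_that("fractional logit recovers the null and respects CI ordering", {
  set.seed(101)
  n <- 600
  df <- data.frame(u = rbinom(n, 10, 0.72) / 10,
                   g = factor(rep(c("a", "b"), each = n / 2)),
                   age = rnorm(n, 35, 10))
  fit <- fractional_logit_means(df, "u", "g", "age")
  expect_s3_class(fit, "cd_adjusted_contrast")
  expect_lt(abs(fit$difference), 0.05)
  expect_true(fit$ci_low <= fit$difference && fit$difference <= fit$ci_high)
  expect_gt(fit$p_value, 0.01)
  expect_equal(sum(fit$adjusted_means * c(1, -1)), fit$difference)
  expect_error(fractional_logit_means(
    data.frame(u = c(-0.1, 0.5), g = factor(c("a", "b"))), "u", "g"), "0, 1")
})

test_that("fractional-logit adjusted means equal group means when saturated", {
  set.seed(33)
  df <- data.frame(u = runif(80), g = factor(rep(c("a", "b"), 40)))
  fit <- fractional_logit_means(df, "u", "g")
  expect_equal(unname(fit$adjusted_means),
               as.numeric(tapply(df$u, df$g, mean)), tolerance = 1e-6)
})

test_that("delta-method gradient agrees with finite differences", {
  skip_if_not_installed("numDeriv")
  set.seed(55)
  n <- 150
  df <- data.frame(u = runif(n), g = factor(sample(c("a", "b"), n, TRUE)),
                   age = rnorm(n))
  fit <- fractional_logit_means(df, "u", "g", "age")
  glmfit <- fit$fit
  X <- model.matrix(glmfit)
  ga <- X; ga[, "gb"] <- 0
  gb <- X; gb[, "gb"] <- 1
  f <- function(beta) mean(plogis(ga %*% beta)) - mean(plogis(gb %*% beta))
  gnum <- numDeriv::grad(f, coef(glmfit))
  se_num <- sqrt(drop(t(gnum) %*% fit$vcov %*% gnum))
  expect_equal(fit$se, se_num, tolerance = 1e-6)
})

test_that("two-part adjusted means equal group means in the saturated model", {
  d <- generate_two_group_costs(c(60, 70), 150, seed = 12)
  fit <- two_part_cost_model(d, "cost", "group")
  expect_equal(unname(fit$adjusted_means),
               as.numeric(tapply(d$cost, d$group, mean)), tolerance = 1e-6)
  expect_equal(fit$difference,
               unname(diff(rev(tapply(d$cost, d$group, mean)))),
               tolerance = 1e-6)
  # lognormal part-2 family also consistent in the saturated case
  fit_ln <- two_part_cost_model(d, "cost", "group", family2 = "lognormal")
  expect_equal(unname(fit_ln$adjusted_means[1]),
               unname(tapply(d$cost, d$group, mean)[1]), tolerance = 0.3)
})

test_that("two-part model handles degenerate cost patterns", {
  allz <- data.frame(cost = rep(0, 40), g = factor(rep(c("a", "b"), 20)))
  fit0 <- two_part_cost_model(allz, "cost", "g")
  expect_equal(unname(fit0$adjusted_means), c(0, 0))
  expect_match(fit0$flag, "zero")

  onez <- data.frame(cost = c(rep(0, 20), rgamma(20, 1, 0.01)),
                     g = factor(rep(c("a", "b"), each = 20)))
  fit1 <- two_part_cost_model(onez, "cost", "g")
  expect_equal(unname(fit1$adjusted_means["a"]), 0)
  expect_match(fit1$flag, "no positive")
  expect_gt(fit1$adjusted_means["b"], 0)

  allpos <- data.frame(cost = rgamma(60, 2, 0.01) + 1,
                       g = factor(rep(c("a", "b"), 30)))
  fit2 <- two_part_cost_model(allpos, "cost", "g")
  expect_match(fit2$flag, "degenerate")
  expect_equal(unname(fit2$adjusted_means),
               as.numeric(tapply(allpos$cost, allpos$g, mean)), tolerance = 1e-6)
  expect_error(two_part_cost_model(
    data.frame(cost = c(-1, 2), g = factor(c("a", "b"))), "cost", "g"),
    "non-negative")
})

test_that("modified Park test recognises the variance family", {
  set.seed(77)
  n <- 800
  x <- runif(n, 1, 3)
  mu <- exp(1 + 0.8 * x)
  dgamma_ <- data.frame(y = rgamma(n, shape = 2, scale = mu / 2), x = x)
  fitg <- glm(y ~ x, data = dgamma_, family = Gamma(link = "log"))
  park_g <- model_selection_diagnostics(fitg)
  expect_equal(park_g$lambda, 2, tolerance = 0.6)
  expect_equal(park_g$recommended, "gamma")

  # log-normal positives: variance power 2 as well, clearly above 1
  dln <- data.frame(y = rlnorm(n, log(mu) - 0.5, 1), x = x)
  fitl <- glm(y ~ x, data = dln, family = Gamma(link = "log"))
  park_l <- model_selection_diagnostics(fitl)
  expect_gt(park_l$lambda - 2 * park_l$se, 1)

  # nearly constant positives: no recommendation
  small <- glm(y ~ 1, data = data.frame(y = rep(5, 8)),
               family = Gamma(link = "log"))
  expect_true(is.na(model_selection_diagnostics(small)$recommended))
})

test_that("robust vcov matches the classical one under homoskedastic gaussian", {
  set.seed(99)
  n <- 4000
  df <- data.frame(x = rnorm(n))
  df$y <- 1 + 2 * df$x + rnorm(n)
  fit <- glm(y ~ x, data = df, family = gaussian())
  vr <- cdburden:::glm_robust_vcov(fit, type = "HC0")
  expect_equal(unname(diag(vr)), unname(diag(vcov(fit))), tolerance = 0.1)
})
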