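## Adjusted subgroup contrasts: fractional-logit and two-part cost models
## with robust (sandwich) variances and delta-method confidence intervals
## for average adjusted predictions.

# Robust (sandwich) covariance for a fitted glm.  HC1 matches the default
# small-sample scaling of Stata's `robust` option.
glm_robust_vcov <- function(fit, type = c("HC1", "HC0")) {
  type <- match.arg(type)
  X <- model.matrix(fit)
  y <- fit$y
  mu <- fitted(fit)
  eta <- fit$linear.predictors
  fam <- fit$family
  me <- fam$mu.eta(eta)
  V <- fam$variance(mu)
  w <- fit$prior.weights
  # score contributions and expected-information bread
  U <- X * ((y - mu) * me / V * w)
  B <- crossprod(X * sqrt(w * me^2 / V))
  Binv <- solve(B)
  meat <- crossprod(U)
  vc <- Binv %*% meat %*% Binv
  if (type == "HC1") {
    n <- nrow(X); k <- ncol(X)
    vc <- vc * n / (n - k)
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  vc
}

# design matrices with the group column forced to each level
group_design <- function(fit, data, group, level) {
  data[[group]] <- factor(level, levels = levels(factor(data[[group]])))
  model.matrix(stats::delete.response(stats::terms(fit)), data)
}

new_adjusted_contrast <- function(means, diff, se, covariates, n,
                                  extra = list()) {
  ci <- diff + c(-1, 1) * qnorm(0.975) * se
  p <- if (is.na(se) || se == 0) NA_real_ else 2 * pnorm(-abs(diff / se))
  out <- list(adjusted_means = means, difference = diff, se = se,
              ci_low = ci[1], ci_high = ci[2], p_value = p,
              covariates = covariates, n = n)
  out <- c(out, extra)
  class(out) <- "cd_adjusted_contrast"
  out
}

#' @export
print.cd_adjusted_contrast <- function(x, ...) {
  cat("Adjusted means (average adjusted predictions):\n")
  print(round(x$adjusted_means, 4))
  cat(sprintf("difference %.4f (95%% CI %.4f to %.4f), p = %.4g, n = %d\n",
              x$difference, x$ci_low, x$ci_high, x$p_value, x$n))
  if (length(x$covariates))
    cat("adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted group means of a fractional outcome (fractional logit)
#'
#' Quasi-likelihood binomial regression with a logit link on an outcome in
#' `[0, 1]` (e.g. a utility index), a two-level group variable and optional
#' covariates.  Group contrasts are reported as average adjusted
#' predictions: predict every observation under each group assignment,
#' average, and build the confidence interval for the difference by the
#' delta method with a robust (HC1) parameter covariance (the quasi-ML
#' variance is misspecified for fractional data, so robust errors are the
#' appropriate default).
#'
#' @param data `data.frame` holding the variables.
#' @param outcome name of the fractional outcome column (values in `[0, 1]`).
#' @param group name of the two-level group column.
#' @param covariates character vector of covariate column names.
#' @return a `cd_adjusted_contrast`: adjusted mean per group, difference
#'   (first level minus second level), delta-method 95% CI and p-value.
#' @export
fractional_logit_means <- function(data, outcome, group,
                                   covariates = character(0)) {
  use <- data[, c(outcome, group, covariates), drop = FALSE]
  use <- use[complete.cases(use), , drop = FALSE]
  y <- use[[outcome]]
  if (any(y < 0 | y > 1)) stop("fractional outcome must lie in [0, 1]")
  use[[group]] <- droplevels(factor(use[[group]]))
  if (nlevels(use[[group]]) != 2) stop("group must have exactly two levels")
  fml <- stats::reformulate(c(group, covariates), response = outcome)
  fit <- glm(fml, data = use, family = quasibinomial("logit"))
  if (!fit$converged) stop("fractional logit did not converge")
  vc <- glm_robust_vcov(fit)
  beta <- coef(fit)
  lev <- levels(use[[group]])
  aap <- grad <- list()
  for (l in lev) {
    Xl <- group_design(fit, use, group, l)
    eta <- drop(Xl %*% beta)
    mu <- plogis(eta)
    aap[[l]] <- mean(mu)
    grad[[l]] <- colMeans(Xl * (mu * (1 - mu)))
  }
  g <- grad[[lev[1]]] - grad[[lev[2]]]
  se <- sqrt(drop(t(g) %*% vc %*% g))
  new_adjusted_contrast(means = unlist(aap),
                        diff = aap[[lev[1]]] - aap[[lev[2]]],
                        se = se, covariates = covariates, n = nrow(use),
                        extra = list(fit = fit, vcov = vc))
}

#' Two-part model for zero-inflated cost outcomes
#'
#' Health-care costs typically mix a large mass of exact zeros with a
#' right-skewed positive distribution, so subgroup contrasts are estimated
#' with a two-part model: a logistic regression for `P(cost > 0)` and a
#' generalised linear model with log link on the positive costs (gamma
#' family by default, selectable via [model_selection_diagnostics()]).  The
#' expected cost of observation *i* is `p_i * m_i`; group contrasts are
#' average adjusted predictions under each group assignment, with the
#' delta-method variance combining both parts (treated as independent, the
#' standard two-part assumption) using robust (HC1) parameter covariances.
#'
#' Degenerate situations are handled explicitly: if no observation is
#' positive both adjusted means are 0; if one group has no positive costs
#' its part-2 prediction is 0 and the result is flagged.
#'
#' @param data `data.frame` holding the variables.
#' @param outcome name of the non-negative cost column.
#' @param group name of the two-level group column.
#' @param covariates covariate column names.
#' @param family2 positive-part family: `"gamma"` (log link) or
#'   `"lognormal"` (Gaussian on `log(cost)`, retransformed with the
#'   smearing-free normal factor).
#' @return a `cd_adjusted_contrast` with element `parts` holding the two
#'   fitted models.
#' @export
two_part_cost_model <- function(data, outcome, group,
                                covariates = character(0),
                                family2 = c("gamma", "lognormal")) {
  family2 <- match.arg(family2)
  use <- data[, c(outcome, group, covariates), drop = FALSE]
  use <- use[complete.cases(use), , drop = FALSE]
  y <- use[[outcome]]
  if (any(y < 0)) stop("costs must be non-negative")
  use[[group]] <- droplevels(factor(use[[group]]))
  if (nlevels(use[[group]]) != 2) stop("group must have exactly two levels")
  lev <- levels(use[[group]])
  n <- nrow(use)
  use$.pos <- as.numeric(y > 0)

  if (all(y == 0))
    return(new_adjusted_contrast(means = setNames(c(0, 0), lev), diff = 0,
                                 se = 0, covariates = covariates, n = n,
                                 extra = list(flag = "all costs zero")))

  pos_by_group <- tapply(use$.pos, use[[group]], sum)
  flag <- NULL
  all_positive <- all(use$.pos == 1)
  if (all_positive) {
    flag <- "no zero costs: probability part degenerate at 1"
    fit1 <- NULL; vc1 <- matrix(0, 1, 1); b1 <- numeric(1)
  } else {
    fml1 <- stats::reformulate(c(group, covariates), response = ".pos")
    fit1 <- glm(fml1, data = use, family = binomial("logit"))
    vc1 <- glm_robust_vcov(fit1)
  }

  pos <- use[use$.pos == 1, , drop = FALSE]
  if (any(pos_by_group == 0)) {
    flag <- paste("group", lev[which(pos_by_group == 0)],
                  "has no positive costs; its mean is 0")
    # part 2 without the group term (inestimable level)
    fml2 <- if (length(covariates))
      stats::reformulate(covariates, response = outcome)
    else stats::reformulate("1", response = outcome)
  } else {
    fml2 <- stats::reformulate(c(group, covariates), response = outcome)
  }
  if (family2 == "gamma") {
    fit2 <- glm(fml2, data = pos, family = Gamma(link = "log"),
                control = list(maxit = 100))
  } else {
    pos$.logy <- log(pos[[outcome]])
    fml2 <- stats::update.formula(fml2, .logy ~ .)
    fit2 <- glm(fml2, data = pos, family = gaussian())
  }
  if ((!all_positive && !fit1$converged) || !fit2$converged)
    stop("two-part model did not converge")
  vc2 <- glm_robust_vcov(fit2)
  if (!all_positive) b1 <- coef(fit1)
  b2 <- coef(fit2)
  sig2 <- if (family2 == "lognormal")
    sum(residuals(fit2)^2) / stats::df.residual(fit2) else 0

  aap <- g1 <- g2 <- list()
  for (l in lev) {
    if (all_positive) {
      X1 <- matrix(0, n, 1)
      p <- rep(1, n)
    } else {
      X1 <- group_design(fit1, use, group, l)
      p <- plogis(drop(X1 %*% b1))
    }
    if (any(pos_by_group == 0) && l == lev[which(pos_by_group == 0)]) {
      aap[[l]] <- 0
      g1[[l]] <- rep(0, length(b1)); g2[[l]] <- rep(0, length(b2))
      next
    }
    X2 <- group_design(fit2, use, group, l)
    m <- exp(drop(X2 %*% b2) + sig2 / 2)
    aap[[l]] <- mean(p * m)
    g1[[l]] <- colMeans(X1 * (m * p * (1 - p)))
    g2[[l]] <- colMeans(X2 * (p * m))
  }
  gg1 <- g1[[lev[1]]] - g1[[lev[2]]]
  gg2 <- g2[[lev[1]]] - g2[[lev[2]]]
  se <- sqrt(drop(t(gg1) %*% vc1 %*% gg1) + drop(t(gg2) %*% vc2 %*% gg2))
  new_adjusted_contrast(means = unlist(aap),
                        diff = aap[[lev[1]]] - aap[[lev[2]]],
                        se = se, covariates = covariates, n = n,
                        extra = list(parts = list(fit1, fit2), flag = flag,
                                     family2 = family2))
}

#' Modified Park test and family recommendation for the positive part
#'
#' Regresses the squared raw residuals of a fitted positive-cost model on
#' the log of its fitted values with a log-link quasi-Poisson GLM.  The
#' slope estimates the power `lambda` in `Var(y | x) ~ E(y | x)^lambda`:
#' about 0 suggests Gaussian, 1 Poisson-like, 2 gamma, 3 inverse Gaussian.
#' With fewer than 10 positive observations no recommendation is made.
#'
#' @param fit a fitted part-2 GLM (log link) — e.g.
#'   `two_part_cost_model(...)$parts[[2]]`.
#' @return `data.frame` with `lambda`, `se`, `recommended`, `loglik`.
#' @export
model_selection_diagnostics <- function(fit) {
  y <- fit$y
  mu <- fitted(fit)
  if (length(y) < 10)
    return(data.frame(lambda = NA_real_, se = NA_real_,
                      recommended = NA_character_,
                      loglik = as.numeric(stats::logLik(fit))))
  res2 <- (y - mu)^2
  if (var(res2) == 0 || var(log(mu)) == 0)
    return(data.frame(lambda = NA_real_, se = NA_real_,
                      recommended = NA_character_,
                      loglik = as.numeric(stats::logLik(fit))))
  park <- glm(res2 ~ log(mu), family = quasipoisson(link = "log"))
  lam <- coef(park)[["log(mu)"]]
  se <- sqrt(glm_robust_vcov(park)["log(mu)", "log(mu)"])
  fam <- c("gaussian", "poisson", "gamma", "inverse_gaussian")
  rec <- fam[which.min(abs(lam - 0:3))]
  data.frame(lambda = lam, se = se, recommended = rec,
             loglik = as.numeric(stats::logLik(fit)))
}
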