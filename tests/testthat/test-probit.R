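test_that("design matrix uses reference-cell coding", {
  cfg <- small_config(n = 300, seed = 14)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, "d1", c("wealth_quintile"))
  expect_equal(ncol(X$X), 1 + 4 + 1)   # intercept + 4 dummies + dimension
  expect_equal(X$reference$wealth_quintile, "poorest")
  expect_equal(colnames(X$X)[ncol(X$X)], "d1")
  # empty covariate list: intercept + dimension only
  X0 <- build_design_matrix(st$tab, "d1", character())
  expect_equal(colnames(X0$X), c("(Intercept)", "d1"))
})

test_that("design matrix drops constants and rejects collinearity", {
  cfg <- small_config(n = 200, seed = 15)
  st <- sim_table(cfg)
  st$tab$const <- "x"
  expect_warning(build_design_matrix(st$tab, "d1", c("const", "residence")),
                 "constant")
  st$tab$res2 <- st$tab$residence
  expect_error(build_design_matrix(st$tab, "d1", c("residence", "res2")),
               "collinear")
  expect_error(build_design_matrix(st$tab, "nope", "residence"),
               "not found")
})

test_that("probit log-likelihood matches direct arithmetic", {
  y <- c(1, 0, 1, 1)
  X <- cbind(1, c(0.5, -1, 2, 0))
  b <- c(0.3, -0.7)
  eta <- X %*% b
  manual <- sum(y * log(pnorm(eta)) + (1 - y) * log(1 - pnorm(eta)))
  expect_equal(probit_loglik(b, y, X), manual, tolerance = 1e-12)
  expect_equal(probit_loglik(c(0, 0), y, X), 4 * log(0.5), tolerance = 1e-14)
  # stable deep in the tail where naive 1 - pnorm underflows
  expect_equal(probit_loglik(10, 1, matrix(4)), pnorm(40, log.p = TRUE))
  expect_lt(probit_loglik(-10, 1, matrix(4)), -700)
  expect_error(probit_loglik(0.1, c(0, 2), cbind(1, 1)), "0/1")
})

test_that("saturated 2x2 probit reproduces the quantile closed form", {
  d <- rep(c(0, 1), each = 50)
  y <- c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(40, 10)))
  X <- cbind("(Intercept)" = 1, d = d)
  fit <- fit_probit(y, X)
  expect_equal(unname(fit$coefficients["d"]), qnorm(0.8) - qnorm(0.2),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), qnorm(0.2),
               tolerance = 1e-6)
  expect_equal(average_predicted_probability(fit, d = 0, dimension = "d"),
               0.2, tolerance = 1e-6)
  expect_equal(average_predicted_probability(fit, d = 1, dimension = "d"),
               0.8, tolerance = 1e-6)
})

test_that("intercept-only probit is the outcome-rate quantile", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_probit(y, matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$coefficients), qnorm(0.3), tolerance = 1e-7)
  expect_equal(average_predicted_probability(fit, d = 0), 0.3,
               tolerance = 1e-7)
  expect_equal(average_predicted_probability(fit, d = 1), 0.3,
               tolerance = 1e-7)
})

test_that("fit_probit agrees with glm's probit fit", {
  cfg <- small_config(n = 1500, seed = 16)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, "d1", fast_covs)
  fit <- fit_probit(st$tab$place_of_delivery, X)
  ref <- glm.fit(X$X, st$tab$place_of_delivery,
                 family = binomial(link = "probit"))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_gte(fit$loglik, probit_loglik(rep(0, ncol(X$X)),
                                       st$tab$place_of_delivery, X))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("relabeling the reference category leaves fitted probabilities", {
  cfg <- small_config(n = 1000, seed = 17)
  st <- sim_table(cfg)
  X1 <- build_design_matrix(st$tab, "d1", "wealth_quintile")
  tab2 <- st$tab
  tab2$wealth_quintile <- relevel(tab2$wealth_quintile, "richest")
  X2 <- build_design_matrix(tab2, "d1", "wealth_quintile")
  f1 <- fit_probit(st$tab$place_of_delivery, X1)
  f2 <- fit_probit(tab2$place_of_delivery, X2)
  p1 <- pnorm(drop(X1$X %*% f1$coefficients))
  p2 <- pnorm(drop(X2$X %*% f2$coefficients))
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fit_probit(rep(1, 20), matrix(1, 20, 1)), "single class")
  y <- rep(c(0, 1), each = 10)
  X <- cbind(1, y)   # index separates classes exactly
  expect_error(fit_probit(y, X), "separation")
})

test_that("probit delta is consistent when the exposure is exogenous", {
  cfg <- sim_config(n = 2e4, rho = 0, seed = 18)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, "d1", names(default_covariate_spec()))
  fit <- fit_probit(st$tab$place_of_delivery, X)
  expect_lt(abs(fit$coefficients[["d1"]] - 1), 0.1)
})

test_that("counterfactual and subgroup predictions differ as expected", {
  cfg <- small_config(n = 2000, seed = 19)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, "d1", fast_covs)
  fit <- fit_probit(st$tab$place_of_delivery, X)
  p0 <- average_predicted_probability(fit, d = 0)
  p1 <- average_predicted_probability(fit, d = 1)
  expect_true(p0 >= 0 && p1 <= 1)
  expect_gt(p1, p0)   # positive delta-hat
  s1 <- average_predicted_probability(fit, d = 1, type = "subgroup")
  expect_equal(s1, mean(pnorm(drop(X$X[X$X[, "d1"] == 1, ] %*%
                                     fit$coefficients))))
  expect_error(average_predicted_probability(fit, d = 2), "0 or 1")
})
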