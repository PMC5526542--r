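test_that("biprobit log-likelihood factorizes at rho = 0", {
  cfg <- small_config(n = 600, seed = 22)
  st <- sim_table(cfg)
  tab <- st$tab
  X <- build_design_matrix(tab, NULL, fast_covs)
  pO <- ncol(X$X) + 1; pE <- ncol(X$X) + 1
  set.seed(5)
  bO <- rnorm(pO, 0, 0.4); bE <- rnorm(pE, 0, 0.4)
  ll_joint <- biprobit_loglik(c(bO, bE, 0), tab$place_of_delivery, tab$d1,
                              X, tab$first_trimester)
  XO <- cbind(X$X, E = tab$d1)
  XE <- cbind(X$X, IV = tab$first_trimester)
  ll_sep <- probit_loglik(bO, tab$place_of_delivery, XO) +
    probit_loglik(bE, tab$d1, XE)
  expect_equal(ll_joint, ll_sep, tolerance = 1e-10)
  # all-zero parameters: each row contributes log Phi2(0,0,0) = log 1/4
  np <- pO + pE + 1
  expect_equal(biprobit_loglik(rep(0, np), tab$place_of_delivery, tab$d1,
                               X, tab$first_trimester),
               nrow(tab) * log(0.25), tolerance = 1e-12)
})

test_that("biprobit log-likelihood matches per-row Phi2 arithmetic", {
  O <- c(1, 0, 1); E <- c(0, 1, 1); Z <- c(1, 0, 1)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  par <- c(-0.2, 0.9, 0.1, 0.7, atanh(-0.3))
  qO <- 2 * O - 1; qE <- 2 * E - 1
  manual <- sum(log(bvn_cdf(qO * (-0.2 + 0.9 * E),
                            qE * (0.1 + 0.7 * Z),
                            qO * qE * (-0.3))))
  expect_equal(biprobit_loglik(par, O, E, X, Z), manual, tolerance = 1e-12)
})

test_that("the four cell probabilities of each row sum to one", {
  X <- matrix(1, 1, 1)
  par <- c(0.4, 1.1, -0.3, 0.8, atanh(0.5))
  for (z in 0:1) {
    tot <- 0
    for (o in 0:1) for (e in 0:1) {
      tot <- tot + exp(biprobit_loglik(par, o, e, X, z))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("the instrument may not enter the outcome design", {
  cfg <- small_config(n = 200, seed = 23)
  st <- sim_table(cfg)
  X <- cbind(1, st$tab$first_trimester)
  expect_error(
    biprobit_loglik(rep(0, 7), st$tab$place_of_delivery, st$tab$d1, X,
                    st$tab$first_trimester),
    "exclusion")
})

test_that("with rho fixed at zero the biprobit reduces to two probits", {
  cfg <- small_config(n = 1200, seed = 24)
  st <- sim_table(cfg)
  tab <- st$tab
  X <- build_design_matrix(tab, NULL, fast_covs)
  bp <- fit_biprobit(tab$place_of_delivery, tab$d1, X, tab$first_trimester,
                     fix_rho = 0)
  pO <- fit_probit(tab$place_of_delivery, cbind(X$X, E = tab$d1))
  pE <- fit_probit(tab$d1, cbind(X$X, IV = tab$first_trimester))
  expect_lt(max(abs(bp$coefficients[bp$idx_outcome] - pO$coefficients)),
            1e-6)
  expect_lt(max(abs(bp$coefficients[bp$idx_treatment] - pE$coefficients)),
            1e-6)
  expect_equal(bp$rho, 0)
})

test_that("free-rho fit improves on the independent-probit start", {
  cfg <- small_config(n = 1500, seed = 25)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, NULL, fast_covs)
  bp <- fit_biprobit(st$tab$place_of_delivery, st$tab$d1, X,
                     st$tab$first_trimester)
  expect_gte(bp$loglik, bp$loglik_independent - 1e-8)
  expect_true(abs(bp$rho) < 1)
  expect_true(all(eigen((bp$vcov + t(bp$vcov)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("under exogeneity the biprobit delta matches the naive probit", {
  cfg <- sim_config(n = 12000, rho = 0, seed = 26)
  st <- sim_table(cfg)
  tab <- st$tab
  Xd <- build_design_matrix(tab, "d1", fast_covs)
  Xc <- build_design_matrix(tab, NULL, fast_covs)
  pr <- fit_probit(tab$place_of_delivery, Xd)
  bp <- fit_biprobit(tab$place_of_delivery, tab$d1, Xc, tab$first_trimester)
  kO <- length(bp$idx_outcome)
  expect_lt(abs(bp$coefficients[[kO]] - pr$coefficients[["d1"]]),
            2 * bp$se[[kO]])
})

test_that("negative error correlation biases the naive probit downward", {
  cfg <- sim_config(n = 12000, rho = -0.4, seed = 27)
  st <- sim_table(cfg)
  tab <- st$tab
  Xd <- build_design_matrix(tab, "d1", fast_covs)
  Xc <- build_design_matrix(tab, NULL, fast_covs)
  pr <- fit_probit(tab$place_of_delivery, Xd)
  bp <- fit_biprobit(tab$place_of_delivery, tab$d1, Xc, tab$first_trimester)
  kO <- length(bp$idx_outcome)
  expect_lt(pr$coefficients[["d1"]], bp$coefficients[[kO]])
  expect_lt(bp$rho, 0)
  w <- wald_exogeneity_test(bp)
  expect_equal(w$label, "rho<0")
  expect_equal(w$statistic, (bp$atanh_rho / bp$se_atanh_rho)^2)
})

test_that("wald label reads rho = 0 when the test cannot reject", {
  fake <- structure(list(converged = TRUE, atanh_rho = 0.01,
                         se_atanh_rho = 0.5, rho = tanh(0.01)),
                    class = "biprobit_fit")
  w <- wald_exogeneity_test(fake)
  expect_equal(w$label, "rho = 0")
  expect_gt(w$p_value, 0.05)
  fake$se_atanh_rho <- 0
  expect_error(wald_exogeneity_test(fake), "standard error")
})

test_that("counterfactual biprobit probabilities are coherent", {
  cfg <- small_config(n = 2500, seed = 28)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, NULL, fast_covs)
  bp <- fit_biprobit(st$tab$place_of_delivery, st$tab$d1, X,
                     st$tab$first_trimester)
  p0 <- average_predicted_probability_biprobit(bp, d = 0)
  p1 <- average_predicted_probability_biprobit(bp, d = 1)
  expect_true(all(c(p0, p1) >= 0 & c(p0, p1) <= 1))
  kO <- length(bp$idx_outcome)
  if (bp$coefficients[[kO]] > 0) expect_gt(p1, p0)
  expect_error(average_predicted_probability_biprobit(bp, d = 0.5),
               "0 or 1")
})

test_that("weak and missing instruments are flagged", {
  cfg <- small_config(n = 1500, seed = 29, gamma_iv = 0.02)
  st <- sim_table(cfg)
  X <- build_design_matrix(st$tab, NULL, "residence")
  expect_warning(
    fit_biprobit(st$tab$place_of_delivery, st$tab$d1, X,
                 st$tab$first_trimester),
    "weak instrument")
  expect_error(
    fit_biprobit(st$tab$place_of_delivery, st$tab$d1, X,
                 rep(1, nrow(st$tab))),
    "variation")
})
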