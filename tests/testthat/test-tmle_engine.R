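test_that("propensity bound follows the 5/(sqrt(n) log n) rule", {
  expect_equal(propensity_bound(5735), 5 / (sqrt(5735) * log(5735)))
  expect_equal(propensity_bound(100), 5 / (10 * log(100)))
  expect_error(propensity_bound(7), class = "dctmle_sample_size_error")
})

test_that("clever covariates vanish on the opposite arm", {
  h <- clever_covariates(c(1, 0), c(0.5, 0.2))
  expect_equal(h$h1, c(2, 0))
  expect_equal(h$h0, c(0, 1.25))

  # IPW normalisation: under the true propensity, mean(h1) ~ 1
  withr::with_seed(4, {
    prop <- stats::runif(5000, 0.2, 0.8)
    a <- stats::rbinom(5000, 1, prop)
  })
  h1 <- clever_covariates(a, prop)$h1
  se <- stats::sd(h1) / sqrt(5000)
  expect_lt(abs(mean(h1) - 1), 3 * se)
})

test_that("fluctuation is exactly zero when the offset already fits", {
  withr::with_seed(5, {
    mu_a <- stats::runif(40, 0.2, 0.8)
    a <- stats::rbinom(40, 1, 0.5)
    pi_hat <- stats::runif(40, 0.3, 0.7)
  })
  h <- clever_covariates(a, pi_hat)
  fl <- fit_fluctuation(mu_a, h$h1, h$h0, mu_a)
  expect_lt(abs(fl$eps1), 1e-8)
  expect_lt(abs(fl$eps0), 1e-8)
})

test_that("fluctuation coefficients match a hand-rolled IRLS oracle", {
  y_star <- c(0.20, 0.80, 0.50, 0.90, 0.10, 0.60)
  a <- c(1, 0, 1, 0, 1, 0)
  pi_hat <- c(0.70, 0.40, 0.55, 0.30, 0.80, 0.50)
  mu_a <- c(0.30, 0.60, 0.50, 0.70, 0.20, 0.40)
  h <- clever_covariates(a, pi_hat)

  fl <- fit_fluctuation(y_star, h$h1, h$h0, mu_a)
  oracle <- oracle_irls_offset(y_star, cbind(h$h1, h$h0),
                               stats::qlogis(mu_a))
  expect_equal(fl$eps1, oracle[1], tolerance = 1e-6)
  expect_equal(fl$eps0, oracle[2], tolerance = 1e-6)
})

test_that("fluctuation stays finite with a nearly empty arm", {
  withr::with_seed(6, {
    n <- 30
    a <- c(1, 1, rep(0, n - 2))
    pi_hat <- stats::runif(n, 0.1, 0.3)
    mu_a <- stats::runif(n, 0.3, 0.7)
    y_star <- stats::runif(n)
  })
  h <- clever_covariates(a, pi_hat)
  fl <- fit_fluctuation(y_star, h$h1, h$h0, mu_a)
  expect_true(is.finite(fl$eps1) && is.finite(fl$eps0))
})

test_that("prediction update: identity at zero, closed form otherwise", {
  mu1 <- c(0.5, 0.3)
  mu0 <- c(0.4, 0.6)
  pi_hat <- c(0.5, 0.25)
  id <- update_predictions(mu1, mu0, pi_hat,
                           list(eps1 = 0, eps0 = 0, weighted = FALSE))
  expect_equal(id$mu1, mu1)
  expect_equal(id$mu0, mu0)

  up <- update_predictions(0.5, 0.5, 0.5,
                           list(eps1 = 0.1, eps0 = 0, weighted = FALSE))
  expect_equal(up$mu1, stats::plogis(0.2))

  big <- update_predictions(mu1, mu0, pi_hat,
                            list(eps1 = 8, eps0 = -8, weighted = FALSE))
  expect_true(all(big$mu1 > 0 & big$mu1 < 1 & big$mu0 > 0 & big$mu0 < 1))
})

test_that("local ATE equals the element-wise back-transformed mean difference", {
  sc <- outcome_scale(kind = "continuous", y_min = 0, y_max = 10)
  expect_equal(local_ate(rep(0.6, 5), rep(0.4, 5), sc), 2.0)
  expect_equal(local_ate(rep(0.3, 4), rep(0.3, 4), sc), 0)

  withr::with_seed(7, {
    mu1 <- stats::runif(60)
    mu0 <- stats::runif(60)
  })
  sc2 <- outcome_scale(kind = "continuous", y_min = 2, y_max = 9)
  expect_equal(local_ate(mu1, mu0, sc2),
               mean(unscale_outcome(mu1, sc2) - unscale_outcome(mu0, sc2)))
})

test_that("EIF variance matches its defining formula", {
  y <- c(3, 7, 5, 2)
  a <- c(1, 0, 1, 0)
  pi_hat <- c(0.6, 0.3, 0.7, 0.4)
  mu1 <- c(4, 6, 5, 3)
  mu0 <- c(2, 5, 4, 2.5)
  ate <- 1.2
  eic <- (a / pi_hat - (1 - a) / (1 - pi_hat)) *
    (y - ifelse(a == 1, mu1, mu0)) + mu1 - mu0 - ate
  expect_equal(eif_variance(y, a, pi_hat, mu1, mu0, ate),
               stats::var(eic) / 4)

  # degenerate: no residual and constant effect => zero variance
  y0 <- ifelse(a == 1, mu1, mu1 - 2)
  expect_equal(eif_variance(y0, a, pi_hat, mu1, mu1 - 2, 2), 0)
  expect_error(eif_variance(1, 1, 0.5, 1, 1, 0),
               class = "dctmle_estimation_error")
})

test_that("with true nuisance models the split estimate is consistent", {
  theta <- 2
  errs <- numeric(0)
  for (n in c(500, 2000, 8000)) {
    gen <- generate_dataset(dgp_config(n = n, true_ate = theta, seed = 100 + n))
    d <- gen$dataset
    sc <- dctmle:::dataset_scale(d)
    rng <- sc$y_max - sc$y_min
    truth <- gen$truth
    exp_model <- oracle_model(local({
      pr <- truth$propensity
      function(x) pr[match(x[, 1], d$L[, 1])]
    }))
    out_model <- oracle_model(local({
      m1s <- (truth$mu1 - sc$y_min) / rng
      m0s <- (truth$mu0 - sc$y_min) / rng
      function(x) {
        idx <- match(x[, 2], d$L[, 1])  # column 1 of x is the forced A
        ifelse(x[, 1] == 1, m1s[idx], m0s[idx])
      }
    }))
    est <- run_split_tmle(d, seq_len(d$n), exp_model, out_model, sc)
    expect_equal(est$n_eval, d$n)
    expect_lt(abs(est$ate_local - theta), 4 * sqrt(est$var_local))
    errs <- c(errs, abs(est$ate_local - theta))
  }
  expect_lt(errs[3], errs[1] + 0.05)
})

test_that("zero fluctuation reduces the pipeline to g-computation", {
  # outcome generated exactly at the model's predictions => eps = 0 and the
  # local ATE equals the plain g-computation mean difference
  withr::with_seed(9, {
    n <- 150
    L <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "X1"))
    a <- stats::rbinom(n, 1, 0.5)
  })
  mu_fun <- function(A, l) stats::plogis(0.3 * A + 0.4 * l)
  sc <- outcome_scale(kind = "continuous", y_min = 0, y_max = 10)
  y <- unscale_outcome(mu_fun(a, L[, 1]), sc)
  d <- analytic_dataset(y, a, L, outcome_kind = "continuous")
  exp_model <- oracle_model(function(x) rep(0.5, nrow(x)))
  out_model <- oracle_model(function(x) mu_fun(x[, 1], x[, 2]))

  est <- run_split_tmle(d, seq_len(n), exp_model, out_model, sc)
  gcomp <- unscale_ate(mean(mu_fun(1, L[, 1]) - mu_fun(0, L[, 1])), sc)
  expect_equal(est$ate_local, gcomp, tolerance = 1e-8)
  expect_lt(abs(est$eps[["eps1"]]), 1e-7)
})

test_that("the weighted fluctuation variant agrees with the covariate variant", {
  withr::with_seed(13, {
    n <- 400
    L <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "X1"))
    prop <- stats::plogis(0.5 * L[, 1])
    a <- stats::rbinom(n, 1, prop)
    mu <- stats::plogis(-0.2 + 0.4 * a + 0.3 * L[, 1])
    y <- unscale_outcome(pmin(pmax(mu + stats::rnorm(n, sd = 0.1), 0.01),
                              0.99),
                         outcome_scale(kind = "continuous", y_min = 0,
                                       y_max = 10))
  })
  sc <- outcome_scale(kind = "continuous", y_min = 0, y_max = 10)
  d <- analytic_dataset(y, a, L, outcome_kind = "continuous")
  exp_model <- oracle_model(function(x) stats::plogis(0.5 * x[, 1]))
  out_model <- oracle_model(function(x) {
    stats::plogis(-0.2 + 0.4 * x[, 1] + 0.3 * x[, 2])
  })
  est_cov <- run_split_tmle(d, seq_len(n), exp_model, out_model, sc)
  est_wt <- run_split_tmle(d, seq_len(n), exp_model, out_model, sc,
                           weighted_fluctuation = TRUE)
  expect_true(is.finite(est_wt$ate_local))
  # asymptotically equivalent parameterisations: close but not identical
  expect_lt(abs(est_wt$ate_local - est_cov$ate_local), 0.2)
  expect_false(identical(est_wt$ate_local, est_cov$ate_local))
})

test_that("a one-armed evaluation split raises a degenerate-split error", {
  d <- make_linear_dataset(60, seed = 10)
  rows <- which(d$a == 1)
  m <- oracle_model(function(x) rep(0.5, nrow(x)))
  mo <- oracle_model(function(x) rep(0.5, nrow(x)))
  expect_error(run_split_tmle(d, rows, m, mo, dctmle:::dataset_scale(d)),
               class = "dctmle_degenerate_split_error")
})
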