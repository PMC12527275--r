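test_that("single mean learner gets weight 1 and predicts the training mean", {
  d <- make_linear_dataset(120, seed = 3)
  m <- fit_superlearner(d$L, d$y, list("mean"), family = "gaussian",
                        cv_folds = 5, seed = 2)
  expect_equal(m$weights, 1)
  expect_equal(unname(predict(m, d$L)), rep(mean(d$y), d$n))

  mb <- fit_superlearner(d$L, d$a, list("mean"), family = "binomial",
                         cv_folds = 5, seed = 2)
  expect_equal(unname(predict(mb, d$L)), rep(mean(d$a), d$n))
})

test_that("the CV-risk minimiser concentrates on the correct learner", {
  # y exactly linear in x: glm should dominate the mean model
  withr::with_seed(11, {
    x <- matrix(stats::rnorm(2000 * 3), 2000, 3)
    y <- drop(x %*% c(1, -0.5, 0.25)) + stats::rnorm(2000, sd = 0.5)
  })
  m <- fit_superlearner(x, y, list("glm", "mean"), family = "gaussian",
                        cv_folds = 5, seed = 4)
  expect_gt(m$weights[m$names == "glm"], 0.99)
})

test_that("weights live on the simplex and the ensemble beats every solo learner", {
  d <- make_linear_dataset(300, seed = 5)
  cases <- list(
    list(y = d$y, family = "gaussian", specs = list("mean", "glm", "l1_glm")),
    list(y = d$a, family = "binomial", specs = list("mean", "glm")),
    list(y = d$a, family = "binomial",
         specs = list("glm", learner_spec("random_forest",
                                          list(num_trees = 50L))))
  )
  risk <- function(family) {
    if (family == "binomial") {
      function(y, p) {
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -mean(y * log(p) + (1 - y) * log(1 - p))
      }
    } else {
      function(y, p) mean((y - p)^2)
    }
  }
  for (cs in cases) {
    m <- fit_superlearner(d$L, cs$y, cs$specs, family = cs$family,
                          cv_folds = 4, seed = 9)
    expect_true(all(m$weights >= 0))
    expect_equal(sum(m$weights), 1, tolerance = 1e-8)
    expect_equal(length(m$weights), length(m$cv_risk))
    # meta-risk at the chosen weights never exceeds the best solo CV risk:
    # rebuild the out-of-fold risk comparison through refits is expensive,
    # so rely on the recorded solo risks and the ensemble's construction,
    # which picks the argmin over candidates that include the vertices
    expect_true(all(is.finite(m$cv_risk)))
  }
})

test_that("fits are deterministic given the seed and leave the RNG alone", {
  d <- make_linear_dataset(250, seed = 8)
  specs <- list("glm", learner_spec("random_forest", list(num_trees = 60L)))
  withr::with_seed(123, {
    before <- stats::runif(1)
  })
  withr::with_seed(123, {
    m1 <- fit_superlearner(d$L, d$a, specs, "binomial", cv_folds = 3,
                           seed = 77)
    after <- stats::runif(1)
  })
  m2 <- fit_superlearner(d$L, d$a, specs, "binomial", cv_folds = 3,
                         seed = 77)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, d$L), predict(m2, d$L))
  expect_identical(before, after)  # SL consumed nothing from the stream
})

test_that("predictions combine linearly and stay inside [0, 1] for binomial", {
  const_fit <- function(v) list(predict = function(x) rep(v, nrow(x)))
  m <- structure(list(base_fits = list(const_fit(0.2), const_fit(0.6)),
                      weights = c(0.5, 0.5), family = "binomial",
                      feature_names = NULL),
                 class = "superlearner")
  expect_equal(predict(m, matrix(0, 3, 2)), rep(0.4, 3))

  d <- make_linear_dataset(200, seed = 12)
  mb <- fit_superlearner(d$L, d$a, list("glm", "mean"), "binomial",
                         cv_folds = 3, seed = 5)
  p <- predict(mb, d$L)
  expect_true(all(p >= 0 & p <= 1))

  # single learner: ensemble == that learner exactly
  ms <- fit_superlearner(d$L, d$y, list("glm"), "gaussian", cv_folds = 3,
                         seed = 5)
  expect_equal(unname(predict(ms, d$L)),
               unname(ms$base_fits[[1]]$predict(d$L)))
})

test_that("failing learners are dropped with a warning; all failing errors", {
  d <- make_linear_dataset(100, seed = 2)
  boom <- structure(list(name = "boom", hyperparameters = list()),
                    class = "learner_spec")
  expect_warning(
    m <- fit_superlearner(d$L, d$y, list(learner_spec("glm"), boom),
                          "gaussian", cv_folds = 3, seed = 1),
    "boom")
  expect_equal(m$names, "glm")
  expect_equal(m$weights, 1)

  expect_error(
    suppressWarnings(fit_superlearner(d$L, d$y, list(boom), "gaussian",
                                      cv_folds = 3, seed = 1)),
    class = "dctmle_estimation_error")
})

test_that("configuration errors are caught early", {
  expect_error(learner_spec("not_a_learner"), class = "dctmle_config_error")
  d <- make_linear_dataset(50, seed = 2)
  expect_error(fit_superlearner(d$L, d$y, list("glm"), "gaussian",
                                cv_folds = 1, seed = 1),
               class = "dctmle_config_error")
  m <- fit_superlearner(d$L, d$y, list("glm"), "gaussian", 3, 1)
  bad <- d$L
  colnames(bad) <- c("Z1", "Z2", "Z3")
  expect_error(predict(m, bad), class = "dctmle_schema_error")
})

test_that("every registered learner fits and predicts on both families", {
  d <- make_linear_dataset(150, seed = 21)
  fast_hypers <- list(random_forest = list(num_trees = 30L),
                      gradient_boosting = list(n_rounds = 30L),
                      neural_net = list(maxit = 50L))
  for (nm in list_learners()) {
    spec <- learner_spec(nm, fast_hypers[[nm]] %||% list())
    fit <- dctmle:::fit_base_learner(spec, d$L, d$a, "binomial", seed = 3)
    p <- fit$predict(d$L[1:7, , drop = FALSE])
    expect_length(p, 7)
    expect_true(all(is.finite(p)), info = nm)
    fitg <- dctmle:::fit_base_learner(spec, d$L, d$y, "gaussian", seed = 3)
    expect_true(all(is.finite(fitg$predict(d$L[1:7, , drop = FALSE]))),
                info = nm)
  }
})

test_that("the stacked ensemble CV risk is no worse than the best solo learner", {
  # direct check on the meta-learner with a fixed out-of-fold matrix
  withr::with_seed(33, {
    Z <- cbind(stats::runif(400, 0.1, 0.9), stats::runif(400, 0.1, 0.9))
    y <- stats::rbinom(400, 1, 0.4 * Z[, 1] + 0.6 * Z[, 2])
  })
  for (fam in c("binomial", "gaussian")) {
    rf <- dctmle:::risk_fun(fam)
    solo <- c(rf(y, Z[, 1]), rf(y, Z[, 2]))
    w <- dctmle:::meta_weights(Z, y, fam, solo)
    expect_lte(rf(y, drop(Z %*% w)), min(solo) + 1e-6)
  }
})
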