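# Base-learner registry for the stacking ensemble.
#
# Every learner is a function(x, y, family, hyper, seed) returning a list
# with a `predict(newx)` closure (probability scale for binomial).  All
# learners are deterministic given `seed` and never touch the caller's RNG
# stream.  The tree learners are backed by the package's own histogram CART
# code in src/, because the targeting theory motivating sample splitting is
# aimed precisely at such non-Donsker learners.

#' Specify a base learner for the stacking ensemble
#'
#' @param name One of `"mean"`, `"glm"`, `"l1_glm"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"spline_gam"`, `"neural_net"`.
#' @param hyperparameters Named list overriding the learner's defaults
#'   (see Details).
#'
#' @details Defaults: `l1_glm` selects its lasso penalty by internal 5-fold
#'   cross-validation over a 30-value path; `random_forest` grows 500 trees
#'   with at least 20 observations per leaf; `gradient_boosting` runs up to
#'   500 depth-3 rounds at learning rate 0.1 with 20-round early stopping on
#'   a held-out tenth; `spline_gam` uses fixed-df (4) cubic regression
#'   splines; `neural_net` is a single hidden layer of 2 tanh units with
#'   weight decay 0.01.
#'
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, hyperparameters = list()) {
  if (!name %in% names(learner_registry)) {
    stop_dctmle(sprintf("unknown learner '%s'; registered learners: %s",
                        name, paste(names(learner_registry), collapse = ", ")),
                "dctmle_config_error")
  }
  structure(list(name = name, hyperparameters = hyperparameters),
            class = "learner_spec")
}

#' List the registered base learners
#' @return Character vector of learner names.
#' @export
list_learners <- function() names(learner_registry)

as_learner_specs <- function(specs) {
  if (inherits(specs, "learner_spec")) specs <- list(specs)
  lapply(specs, function(s) {
    if (inherits(s, "learner_spec")) s else learner_spec(as.character(s))
  })
}

hyper <- function(h, name, default) h[[name]] %||% default

# ---- individual learners ---------------------------------------------------

fit_mean_learner <- function(x, y, family, h, seed) {
  m <- mean(y)
  list(predict = function(newx) rep(m, nrow(newx)))
}

glm_linkinv <- function(family) {
  if (family == "binomial") stats::binomial()$linkinv else identity
}

fit_glm_learner <- function(x, y, family, h, seed) {
  fam <- if (family == "binomial") stats::quasibinomial() else stats::gaussian()
  X <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = fam))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  linkinv <- glm_linkinv(family)
  list(predict = function(newx) {
    linkinv(drop(cbind(1, newx) %*% beta))
  })
}

# Lasso with the penalty chosen by an internal cross-validation loop over a
# shared lambda path.  glmnet does the path fitting; the loop here only
# scores held-out deviance, which avoids cv.glmnet's per-fold prediction
# overhead (an order of magnitude for small n).
fit_l1_glm_learner <- function(x, y, family, h, seed) {
  if (ncol(x) < 2L) return(fit_glm_learner(x, y, family, h, seed))
  nlambda <- hyper(h, "nlambda", 30L)
  nfolds <- hyper(h, "internal_folds", 5L)
  fam <- if (family == "binomial") "binomial" else "gaussian"
  if (fam == "binomial" && length(unique(y)) > 2L) fam <- "gaussian"

  full <- glmnet::glmnet(x, y, family = fam, nlambda = nlambda,
                         alpha = hyper(h, "alpha", 1))
  lam <- full$lambda
  linkinv <- glm_linkinv(if (fam == "binomial") "binomial" else "gaussian")
  # response predictions for a whole path, without glmnet's S4 dispatch
  path_response <- function(fit, newx) {
    eta <- sweep(newx %*% as.matrix(fit$beta), 2, fit$a0, "+")
    linkinv(eta)
  }
  n <- nrow(x)
  foldid <- with_local_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  risk <- risk_fun(family)
  cvloss <- matrix(NA_real_, nfolds, length(lam))
  for (v in seq_len(nfolds)) {
    hold <- foldid == v
    fv <- tryCatch(
      glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold], family = fam,
                     lambda = lam, alpha = hyper(h, "alpha", 1)),
      error = function(e) NULL)
    if (is.null(fv)) next
    pred <- path_response(fv, x[hold, , drop = FALSE])
    # a fold fit may stop early along the path; align on fitted lambdas
    kk <- ncol(pred)
    cvloss[v, seq_len(kk)] <- vapply(seq_len(kk),
                                     function(j) risk(y[hold], pred[, j]),
                                     numeric(1))
  }
  mean_loss <- colMeans(cvloss)
  usable <- which(is.finite(mean_loss))
  j_best <- if (length(usable)) usable[which.min(mean_loss[usable])] else length(lam)
  beta_best <- as.numeric(full$beta[, j_best])
  a0_best <- full$a0[j_best]
  list(lambda = lam[j_best], predict = function(newx) {
    linkinv(drop(newx %*% beta_best) + a0_best)
  })
}

fit_random_forest_learner <- function(x, y, family, h, seed) {
  p <- ncol(x)
  mtry <- hyper(h, "mtry",
                if (family == "binomial") max(1L, floor(sqrt(p)))
                else max(1L, floor(p / 3)))
  fit <- .rf_fit_cpp(x, y,
                     num_trees = hyper(h, "num_trees", 500L),
                     mtry = as.integer(mtry),
                     min_leaf = hyper(h, "min_leaf", 20L),
                     max_depth = hyper(h, "max_depth", 25L),
                     sample_fraction = hyper(h, "sample_fraction", 1.0),
                     bootstrap = hyper(h, "bootstrap", TRUE),
                     max_bins = hyper(h, "max_bins", 64L),
                     seed = as.integer(seed))
  clip <- family == "binomial"
  list(predict = function(newx) {
    p <- .rf_predict_cpp(fit, newx)
    if (clip) clamp(p, 0, 1) else p
  })
}

fit_gradient_boosting_learner <- function(x, y, family, h, seed) {
  fit <- .gbm_fit_cpp(x, y,
                      family = if (family == "binomial") 1L else 0L,
                      n_rounds = hyper(h, "n_rounds", 500L),
                      shrinkage = hyper(h, "shrinkage", 0.1),
                      max_depth = hyper(h, "max_depth", 3L),
                      min_leaf = hyper(h, "min_leaf", 10L),
                      valid_fraction = hyper(h, "valid_fraction", 0.1),
                      patience = hyper(h, "patience", 20L),
                      max_bins = hyper(h, "max_bins", 64L),
                      seed = as.integer(seed))
  list(predict = function(newx) .gbm_predict_cpp(fit, newx))
}

# Additive model with fixed-df natural cubic splines on continuous columns;
# near-discrete columns (indicators) enter linearly.  Fixed-df additive
# smooths are an ordinary (quasi-)GLM on the expanded basis, so the basis
# is built directly with splines::ns and fitted with glm.fit; knots are
# frozen from the training data for prediction.
fit_spline_gam_learner <- function(x, y, family, h, seed) {
  df <- hyper(h, "df", 4L)
  p <- ncol(x)
  nuniq <- apply(x, 2, function(col) length(unique(col)))
  smooth_cols <- which(nuniq > df + 2)
  bases <- lapply(seq_len(p), function(j) {
    if (j %in% smooth_cols) splines::ns(x[, j], df = df) else NULL
  })
  expand <- function(m) {
    do.call(cbind, lapply(seq_len(p), function(j) {
      if (is.null(bases[[j]])) m[, j, drop = FALSE]
      else stats::predict(bases[[j]], m[, j])
    }))
  }
  X <- cbind(1, expand(x))
  fam <- if (family == "binomial") stats::quasibinomial() else stats::gaussian()
  fit <- suppressWarnings(stats::glm.fit(X, y, family = fam))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  linkinv <- glm_linkinv(family)
  list(predict = function(newx) {
    linkinv(drop(cbind(1, expand(newx)) %*% beta))
  })
}

# Single-hidden-layer perceptron (tanh units) trained by BFGS on the
# decay-penalised loss; inputs are standardised internally.
fit_neural_net_learner <- function(x, y, family, h, seed) {
  size <- hyper(h, "size", 2L)
  decay <- hyper(h, "decay", 0.01)
  maxit <- hyper(h, "maxit", 200L)
  p <- ncol(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  n <- nrow(xs)
  binom <- family == "binomial"

  unpack <- function(par) {
    W1 <- matrix(par[seq_len(p * size)], p, size)
    b1 <- par[p * size + seq_len(size)]
    w2 <- par[p * size + size + seq_len(size)]
    b2 <- par[length(par)]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  forward <- function(pp, X) {
    Z <- tanh(sweep(X %*% pp$W1, 2, pp$b1, "+"))
    eta <- drop(Z %*% pp$w2) + pp$b2
    list(Z = Z, eta = eta)
  }
  loss <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp, xs)
    fit_loss <- if (binom) bernoulli_risk(y, expit(fw$eta))
                else mean((y - fw$eta)^2)
    fit_loss + decay * (sum(pp$W1^2) + sum(pp$w2^2))
  }
  grad <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp, xs)
    dldeta <- if (binom) (expit(fw$eta) - y) / n
              else -2 * (y - fw$eta) / n
    gw2 <- drop(crossprod(fw$Z, dldeta)) + 2 * decay * pp$w2
    gb2 <- sum(dldeta)
    dpre <- (dldeta %o% pp$w2) * (1 - fw$Z^2)
    gW1 <- crossprod(xs, dpre) + 2 * decay * pp$W1
    gb1 <- colSums(dpre)
    c(as.vector(gW1), gb1, gw2, gb2)
  }

  init <- with_local_seed(seed,
                          stats::runif(p * size + 2 * size + 1, -0.5, 0.5))
  opt <- stats::optim(init, loss, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  pp <- unpack(opt$par)
  list(predict = function(newx) {
    nxs <- sweep(sweep(newx, 2, mu), 2, sd_, "/")
    eta <- forward(pp, nxs)$eta
    if (binom) expit(eta) else eta
  })
}

learner_registry <- list(
  mean = fit_mean_learner,
  glm = fit_glm_learner,
  l1_glm = fit_l1_glm_learner,
  random_forest = fit_random_forest_learner,
  gradient_boosting = fit_gradient_boosting_learner,
  spline_gam = fit_spline_gam_learner,
  neural_net = fit_neural_net_learner
)

fit_base_learner <- function(spec, x, y, family, seed) {
  fitter <- learner_registry[[spec$name]]
  fit <- fitter(x, y, family, spec$hyperparameters, seed)
  fit$name <- spec$name
  fit
}
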