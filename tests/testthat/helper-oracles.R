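# Independent oracles.  These deliberately re-derive the quantities they
# check from first principles (hand-rolled IRLS, a from-scratch textbook
# targeting pass) and never call into the package's own estimation chain.

# Iteratively reweighted least squares for an intercept-free logistic-link
# quasi-likelihood regression with an offset.
oracle_irls_offset <- function(y, X, offset, max_iter = 200L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- (eta - offset) + (y - mu) / w
    WX <- X * w
    beta_new <- drop(solve(crossprod(X, WX), crossprod(WX, z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# Textbook TMLE for a continuous outcome with plain-GLM nuisance models and
# no sample splitting, written end to end without package estimation code.
oracle_tmle_glm <- function(y, a, L) {
  n <- length(y)
  ymin <- min(y)
  ymax <- max(y)
  ystar <- (y - ymin) / (ymax - ymin)

  dfL <- as.data.frame(L)
  pfit <- stats::glm(a ~ ., data = dfL, family = stats::binomial())
  pi_hat <- stats::predict(pfit, type = "response")
  b <- 5 / (sqrt(n) * log(n))
  pi_hat <- pmin(pmax(pi_hat, b), 1 - b)

  qd <- data.frame(a = a, dfL)
  qfit <- stats::glm(ystar ~ ., data = qd, family = stats::gaussian())
  trunc01 <- function(p) pmin(pmax(pmin(pmax(p, 0), 1), 1e-5), 1 - 1e-5)
  mu1 <- trunc01(stats::predict(qfit, newdata = transform(qd, a = 1)))
  mu0 <- trunc01(stats::predict(qfit, newdata = transform(qd, a = 0)))
  mu_a <- ifelse(a == 1, mu1, mu0)

  h1 <- a / pi_hat
  h0 <- (1 - a) / (1 - pi_hat)
  eps <- oracle_irls_offset(ystar, cbind(h1, h0), stats::qlogis(mu_a))
  mu1_u <- stats::plogis(stats::qlogis(mu1) + eps[1] / pi_hat)
  mu0_u <- stats::plogis(stats::qlogis(mu0) + eps[2] / (1 - pi_hat))
  (ymax - ymin) * mean(mu1_u - mu0_u)
}

# Wrapper class so true (or arbitrary fixed) nuisance functions can stand in
# for fitted models inside run_split_tmle.
oracle_model <- function(f) structure(list(f = f), class = "oracle_model")
predict.oracle_model <- function(object, x, ...) object$f(x)
registerS3method("predict", "oracle_model", predict.oracle_model,
                 envir = asNamespace("stats"))
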