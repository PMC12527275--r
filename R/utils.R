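# Internal numerical and RNG helpers.

expit <- stats::plogis
logit <- stats::qlogis

#' @importFrom withr with_seed
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive `k` reproducible child seeds (< 2^31) from one master seed.
# The whole vector is drawn up front, so results cannot depend on how
# repetitions are distributed over workers.
derive_seeds <- function(master_seed, k) {
  with_local_seed(master_seed, sample.int(2147483646L, k, replace = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Lawson-Hanson active-set non-negative least squares: min ||y - Z b||^2
# subject to b >= 0.  Dimensions here are tiny (one column per base
# learner), so a plain active-set loop is ample.
nnls_fit <- function(Z, y, max_iter = 10 * ncol(Z) + 50, tol = 1e-10) {
  p <- ncol(Z)
  passive <- rep(FALSE, p)
  b <- numeric(p)
  for (iter in seq_len(max_iter)) {
    w <- drop(crossprod(Z, y - Z %*% b))
    w[passive] <- -Inf
    if (all(w <= tol)) break
    passive[which.max(w)] <- TRUE
    repeat {
      s <- numeric(p)
      zp <- Z[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(zp) + diag(1e-12, sum(passive)),
                               crossprod(zp, y)))
      if (all(s[passive] > tol)) {
        b <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(b[neg] / (b[neg] - s[neg]))
      b <- b + alpha * (s - b)
      passive[passive & b <= tol] <- FALSE
      b[!passive] <- 0
    }
  }
  b
}

# quasi-binomial deviance-style risk (mean negative Bernoulli log-likelihood);
# valid for y in [0, 1]
bernoulli_risk <- function(y, p) {
  p <- clamp(p, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

squared_risk <- function(y, p) mean((y - p)^2)

risk_fun <- function(family) {
  if (family == "binomial") bernoulli_risk else squared_risk
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dctmle <- function(msg, class, ...) {
  stop(structure(class = c(class, "dctmle_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
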