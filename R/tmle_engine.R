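# Targeting engine: propensity bounding, clever covariates, logistic
# fluctuation, counterfactual update, local ATE and its efficient-influence
# function (EIF) variance for one evaluation split.

#' Positivity bound for predicted propensities
#'
#' Returns `5 / (sqrt(n) * log(n))`, the symmetric truncation level for the
#' predicted exposure probabilities; callers clip propensities into
#' `[bound, 1 - bound]`.  `n` is the total analytic sample size, not the
#' split size.
#'
#' @param n_total Total number of subjects in the analytic dataset.
#' @return The lower truncation bound (a real in (0, 0.5)).
#' @export
propensity_bound <- function(n_total) {
  b <- 5 / (sqrt(n_total) * log(n_total))
  if (!is.finite(b) || b >= 0.5) {
    stop_dctmle(sprintf("sample too small for propensity bounding (n = %s)",
                        n_total), "dctmle_sample_size_error")
  }
  b
}

#' Clever covariates of the fluctuation regression
#'
#' `h1 = a / pi_hat` for the exposed and `h0 = (1 - a) / (1 - pi_hat)` for
#' the unexposed; each is exactly zero on the opposite arm.
#'
#' @param a 0/1 exposure vector.
#' @param pi_hat Bounded propensity predictions, strictly inside (0, 1).
#' @return List with components `h1` and `h0`.
#' @export
clever_covariates <- function(a, pi_hat) {
  stopifnot(length(a) == length(pi_hat), all(pi_hat > 0 & pi_hat < 1))
  list(h1 = a / pi_hat, h0 = (1 - a) / (1 - pi_hat))
}

#' Fit the logistic fluctuation (influence parameters)
#'
#' Intercept-free maximum-quasi-likelihood logistic regression of the
#' \[0, 1\]-scaled outcome on the two clever covariates with
#' `logit(mu_a)` as offset.  The quasi-binomial likelihood makes this valid
#' for continuous scaled outcomes.
#'
#' @param y_star Scaled outcome on the evaluation split, in \[0, 1\].
#' @param h1,h0 Clever covariates from [clever_covariates()].
#' @param mu_a Initial outcome predictions at the observed exposure,
#'   strictly inside (0, 1).
#' @param weighted If `TRUE`, uses the asymptotically equivalent weighted
#'   parameterisation: arm indicators as covariates and `h1 + h0` as
#'   weights.
#' @param a Exposure vector, required when `weighted = TRUE`.
#' @return List with components `eps1`, `eps0` (finite reals) and
#'   `weighted`.
#' @export
fit_fluctuation <- function(y_star, h1, h0, mu_a, weighted = FALSE,
                            a = NULL) {
  stopifnot(all(mu_a > 0 & mu_a < 1))
  off <- logit(mu_a)
  if (weighted) {
    if (is.null(a)) {
      stop_dctmle("the weighted fluctuation needs the exposure vector",
                  "dctmle_config_error")
    }
    X <- cbind(d1 = a, d0 = 1 - a)
    w <- h1 + h0
  } else {
    X <- cbind(h1 = h1, h0 = h0)
    w <- rep(1, length(y_star))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y_star, weights = w, offset = off,
                   family = stats::quasibinomial(),
                   control = stats::glm.control(maxit = 100L)))
  eps <- fit$coefficients
  eps[is.na(eps)] <- 0
  if (!fit$converged || any(!is.finite(eps))) {
    stop_dctmle("fluctuation regression did not converge",
                "dctmle_fluctuation_error",
                diagnostics = list(converged = fit$converged,
                                   coefficients = eps))
  }
  list(eps1 = unname(eps[1]), eps0 = unname(eps[2]), weighted = weighted)
}

#' Update counterfactual outcome predictions with the influence parameters
#'
#' Both potential-outcome predictions are tilted for every subject using the
#' counterfactual clever covariates `1 / pi_hat` and `1 / (1 - pi_hat)`:
#' `expit(logit(mu1) + eps1 / pi_hat)` and
#' `expit(logit(mu0) + eps0 / (1 - pi_hat))`.  Under the weighted
#' fluctuation the shift is `eps1` / `eps0` alone.
#'
#' @param mu1,mu0 Initial counterfactual predictions, strictly inside (0, 1).
#' @param pi_hat Bounded propensity predictions.
#' @param fit A [fit_fluctuation()] result.
#' @return List with updated `mu1` and `mu0`, each in (0, 1).
#' @export
update_predictions <- function(mu1, mu0, pi_hat, fit) {
  stopifnot(all(mu1 > 0 & mu1 < 1), all(mu0 > 0 & mu0 < 1))
  if (isTRUE(fit$weighted)) {
    list(mu1 = expit(logit(mu1) + fit$eps1),
         mu0 = expit(logit(mu0) + fit$eps0))
  } else {
    list(mu1 = expit(logit(mu1) + fit$eps1 / pi_hat),
         mu0 = expit(logit(mu0) + fit$eps0 / (1 - pi_hat)))
  }
}

#' Split-specific (local) average treatment effect
#'
#' Mean difference of the updated counterfactual predictions on the scaled
#' outcome, back-transformed to the original outcome scale (risk difference
#' for binary outcomes).
#'
#' @param mu1_updated,mu0_updated Updated counterfactual predictions on the
#'   \[0, 1\] scale.
#' @param scale An [outcome_scale()].
#' @return The local ATE on the original outcome scale.
#' @export
local_ate <- function(mu1_updated, mu0_updated, scale) {
  if (!length(mu1_updated)) {
    stop_dctmle("empty evaluation split", "dctmle_estimation_error")
  }
  unscale_ate(mean(mu1_updated - mu0_updated), scale)
}

#' EIF-based variance of a local ATE
#'
#' Computes the efficient influence curve on the original outcome scale,
#' `EIC_i = (a_i/pi_i - (1-a_i)/(1-pi_i)) (y_i - mu_a_i) + mu1_i - mu0_i -
#' ATE_s`, and returns `Var(EIC) / n_eval` using the sample variance.
#'
#' @param y Outcome on the original scale (evaluation split).
#' @param a Exposure vector.
#' @param pi_hat Bounded propensity predictions.
#' @param mu1_u,mu0_u Updated counterfactual predictions on the ORIGINAL
#'   outcome scale.
#' @param ate_local Local ATE on the original scale.
#' @param scale An [outcome_scale()] (kept for interface symmetry; the
#'   inputs are already on the original scale).
#' @param n_total Denominator sample size.  Under cross-fitting this is the
#'   FULL analytic sample size, not the split size: the global ATE averages
#'   S local ATEs that each use n/S rows, so `Var(global) =
#'   (1/S^2) * sum_s Var_s(EIC) / (n/S) = mean_s Var_s(EIC) / n` — i.e.
#'   averaging the S local variances yields a valid variance for the global
#'   ATE exactly when each local variance divides by the full n.  Defaults
#'   to `length(y)` (the no-split case, where the two coincide).
#' @return `Var(EIC) / n_total`.
#' @export
eif_variance <- function(y, a, pi_hat, mu1_u, mu0_u, ate_local,
                         scale = NULL, n_total = length(y)) {
  if (length(y) < 2L) {
    stop_dctmle("EIF variance undefined for fewer than 2 evaluation rows",
                "dctmle_estimation_error")
  }
  mu_a <- ifelse(a == 1, mu1_u, mu0_u)
  eic <- (a / pi_hat - (1 - a) / (1 - pi_hat)) * (y - mu_a) +
    mu1_u - mu0_u - ate_local
  stats::var(eic) / n_total
}

# initial predictions are bounded to [0,1] and then pushed strictly inside
# so that logit() is finite
truncate_unit <- function(p, eps = 1e-5) clamp(p, eps, 1 - eps)

#' Run the targeting steps on one evaluation split
#'
#' Chains propensity prediction, bounding, counterfactual outcome
#' prediction, truncation, clever covariates, fluctuation, update,
#' back-transform, local ATE and EIF variance for one evaluation split,
#' given nuisance models fitted on two different splits (neither overlapping
#' the evaluation rows under cross-fitting; the no-split variant passes the
#' full data everywhere).
#'
#' @param dataset An [analytic_dataset()].
#' @param eval_rows Integer indices of the evaluation split.
#' @param exposure_model Fitted model for `P(A = 1 | L)`; anything with a
#'   `predict(model, x)` method returning probabilities.
#' @param outcome_model Fitted model for `E[Y* | A, L]`; predicts from a
#'   design matrix whose first column is the exposure.
#' @param scale An [outcome_scale()].
#' @param covars_exposure,covars_outcome Covariate column names used by each
#'   nuisance model (defaults: all columns).
#' @param weighted_fluctuation Use the weighted fluctuation variant.
#' @return List of class `split_estimate`: `ate_local`, `var_local`,
#'   `n_eval`, and the fluctuation coefficients `eps`.
#' @export
run_split_tmle <- function(dataset, eval_rows, exposure_model, outcome_model,
                           scale, covars_exposure = NULL,
                           covars_outcome = NULL,
                           weighted_fluctuation = FALSE) {
  stopifnot(inherits(dataset, "analytic_dataset"))
  eval_rows <- as.integer(eval_rows)
  if (!length(eval_rows)) {
    stop_dctmle("empty evaluation split", "dctmle_estimation_error")
  }
  a <- dataset$a[eval_rows]
  if (length(unique(a)) < 2L) {
    stop_dctmle("evaluation split lacks one exposure arm",
                "dctmle_degenerate_split_error")
  }
  y <- dataset$y[eval_rows]
  y_star <- scale_outcome(y, scale)

  LT <- dataset$L[eval_rows, covars_exposure %||% colnames(dataset$L),
                  drop = FALSE]
  LO <- dataset$L[eval_rows, covars_outcome %||% colnames(dataset$L),
                  drop = FALSE]

  # steps 4-5: propensity prediction on the evaluation rows, then bounding
  bound <- propensity_bound(dataset$n)
  pi_hat <- clamp(stats::predict(exposure_model, LT), bound, 1 - bound)

  # step 6: counterfactual outcome predictions, truncated inside (0, 1)
  x1 <- cbind(A = 1, LO)
  x0 <- cbind(A = 0, LO)
  mu1 <- truncate_unit(clamp(stats::predict(outcome_model, x1), 0, 1))
  mu0 <- truncate_unit(clamp(stats::predict(outcome_model, x0), 0, 1))
  mu_a <- ifelse(a == 1, mu1, mu0)

  # steps 7-9: clever covariates, fluctuation, update
  h <- clever_covariates(a, pi_hat)
  fl <- fit_fluctuation(y_star, h$h1, h$h0, mu_a,
                        weighted = weighted_fluctuation, a = a)
  upd <- update_predictions(mu1, mu0, pi_hat, fl)

  # steps 10-12: back-transform, local ATE, EIF variance
  ate_s <- local_ate(upd$mu1, upd$mu0, scale)
  mu1_orig <- unscale_outcome(upd$mu1, scale)
  mu0_orig <- unscale_outcome(upd$mu0, scale)
  var_s <- eif_variance(y, a, pi_hat, mu1_orig, mu0_orig, ate_s, scale,
                        n_total = dataset$n)

  structure(list(ate_local = ate_s, var_local = var_s,
                 n_eval = length(eval_rows),
                 eps = c(eps1 = fl$eps1, eps0 = fl$eps0)),
            class = "split_estimate")
}
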