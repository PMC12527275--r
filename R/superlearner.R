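# Cross-validated stacking ("Super-Learner") for the nuisance models.
#
# V-fold cross-validation produces out-of-fold predictions for every base
# learner; ensemble weights minimise the cross-validated risk (squared error
# for gaussian, negative Bernoulli log-likelihood for binomial) over the
# probability simplex; the surviving learners are then refit on all rows.

#' Fit a cross-validated stacking ensemble
#'
#' @param x Numeric covariate matrix (one row per observation).
#' @param y Response vector; 0/1 (or values in \[0, 1\]) for
#'   `family = "binomial"`.
#' @param specs List of [learner_spec()] objects or learner names.
#' @param family `"binomial"` or `"gaussian"`.  Binomial cross-validation
#'   folds are stratified by the response so every fold contains both
#'   classes; gaussian folds are plain random.
#' @param cv_folds Number of cross-validation folds V (>= 2, <= n).
#' @param seed Integer seed; fits are reproducible and leave the caller's
#'   RNG state untouched.
#'
#' @return Object of class `superlearner`: `base_fits`, simplex `weights`,
#'   per-learner cross-validated risk `cv_risk`, `family`, `cv_folds`,
#'   learner `names`, and the training `feature_names`.
#' @export
fit_superlearner <- function(x, y, specs, family = c("binomial", "gaussian"),
                             cv_folds = 10L, seed = 1L) {
  family <- match.arg(family)
  specs <- as_learner_specs(specs)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (cv_folds < 2L || cv_folds > n) {
    stop_dctmle("cv_folds must be between 2 and the number of rows",
                "dctmle_config_error")
  }
  J <- length(specs)
  lnames <- vapply(specs, `[[`, character(1), "name")

  foldid <- make_cv_folds(y, cv_folds, family, seed)
  learner_seeds <- derive_seeds(seed, J * (cv_folds + 1L))

  # out-of-fold prediction matrix
  Z <- matrix(NA_real_, n, J)
  failed <- rep(FALSE, J)
  for (j in seq_len(J)) {
    for (v in seq_len(cv_folds)) {
      hold <- foldid == v
      fit_v <- tryCatch(
        fit_base_learner(specs[[j]], x[!hold, , drop = FALSE], y[!hold],
                         family, learner_seeds[(j - 1L) * (cv_folds + 1L) + v]),
        error = function(e) e)
      if (inherits(fit_v, "error")) {
        failed[j] <- TRUE
        break
      }
      pred <- tryCatch(fit_v$predict(x[hold, , drop = FALSE]),
                       error = function(e) e)
      if (inherits(pred, "error") || !all(is.finite(pred))) {
        failed[j] <- TRUE
        break
      }
      Z[hold, j] <- pred
    }
  }
  if (any(failed)) {
    warning(sprintf("dropping failed learner(s): %s",
                    paste(lnames[failed], collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(!failed)
  if (!length(keep)) {
    stop_dctmle("all base learners failed", "dctmle_estimation_error")
  }

  risk <- risk_fun(family)
  cv_risk <- vapply(keep, function(j) risk(y, Z[, j]), numeric(1))
  w_keep <- meta_weights(Z[, keep, drop = FALSE], y, family, cv_risk)

  # refit survivors on the full training data
  base_fits <- lapply(seq_along(keep), function(idx) {
    j <- keep[idx]
    fit_base_learner(specs[[j]], x, y, family,
                     learner_seeds[(j - 1L) * (cv_folds + 1L) + cv_folds + 1L])
  })

  structure(list(
    base_fits = base_fits,
    weights = w_keep,
    cv_risk = cv_risk,
    names = lnames[keep],
    dropped = lnames[failed],
    family = family,
    cv_folds = as.integer(cv_folds),
    feature_names = colnames(x)
  ), class = "superlearner")
}

make_cv_folds <- function(y, cv_folds, family, seed) {
  n <- length(y)
  with_local_seed(seed, {
    if (family == "binomial" && all(y %in% c(0, 1))) {
      foldid <- integer(n)
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        foldid[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
      }
      foldid
    } else {
      sample(rep(seq_len(cv_folds), length.out = n))
    }
  })
}

# Simplex-constrained risk minimisation on the out-of-fold predictions.
# Candidates: (i) non-negative least squares scaled to the simplex (the
# canonical gaussian meta-learner), (ii) softmax-parameterised BFGS from a
# uniform start and from the best solo learner, (iii) the vertices
# themselves.  The candidate with the smallest CV risk wins, so the
# ensemble risk never exceeds the best solo risk.
meta_weights <- function(Z, y, family, solo_risk) {
  J <- ncol(Z)
  if (J == 1L) return(1)
  risk <- risk_fun(family)
  obj <- function(w) risk(y, drop(Z %*% w))

  candidates <- list()
  for (j in seq_len(J)) {
    v <- numeric(J); v[j] <- 1
    candidates[[length(candidates) + 1L]] <- v
  }
  if (family == "gaussian") {
    b <- nnls_fit(Z, y)
    if (sum(b) > 1e-12) candidates[[length(candidates) + 1L]] <- b / sum(b)
  }
  softmax <- function(b) { e <- exp(b - max(b)); e / sum(e) }
  for (start in list(rep(0, J),
                     { s <- rep(-10, J); s[which.min(solo_risk)] <- 10; s })) {
    opt <- tryCatch(
      stats::optim(start, function(b) obj(softmax(b)), method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      candidates[[length(candidates) + 1L]] <- softmax(opt$par)
    }
  }
  risks <- vapply(candidates, obj, numeric(1))
  w <- candidates[[which.min(risks)]]
  w <- pmax(w, 0)
  w / sum(w)
}

#' Predict from a fitted stacking ensemble
#'
#' @param object A [fit_superlearner()] result.
#' @param x Covariate matrix with the same column layout as training.
#' @param ... Unused.
#' @return Weighted combination of base-learner predictions; probabilities
#'   are combined on the probability scale and clipped to \[0, 1\] for
#'   `family = "binomial"`.
#' @export
predict.superlearner <- function(object, x, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names)) {
    stop_dctmle("prediction columns do not match the training layout",
                "dctmle_schema_error")
  }
  if (ncol(x) != length(object$feature_names %||% seq_len(ncol(x)))) {
    stop_dctmle("prediction matrix has a different number of columns than training",
                "dctmle_schema_error")
  }
  preds <- vapply(object$base_fits, function(f) f$predict(x),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) preds <- matrix(preds, nrow = 1L)
  out <- drop(preds %*% object$weights)
  if (object$family == "binomial") out <- clamp(out, 0, 1)
  out
}

#' @export
print.superlearner <- function(x, ...) {
  cat(sprintf("<superlearner> family=%s, V=%d\n", x$family, x$cv_folds))
  tab <- data.frame(learner = x$names, weight = round(x$weights, 4),
                    cv_risk = signif(x$cv_risk, 6))
  print(tab, row.names = FALSE)
  if (length(x$dropped)) {
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
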