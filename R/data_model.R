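# Analytic dataset container, outcome scaling, and result (de)serialisation.

#' Construct an analytic dataset
#'
#' Bundles the outcome, the binary exposure and the covariate matrix into a
#' validated container used by every estimation routine.  Missing values are
#' rejected outright: the estimators assume a complete analytic dataset and
#' imputation is out of scope.
#'
#' @param outcome Numeric outcome vector on its original scale (e.g. days of
#'   hospital stay), or 0/1 for a binary outcome.
#' @param exposure Vector of 0/1 exposure indicators; both levels must be
#'   present.
#' @param covariates Numeric matrix (or data frame of numeric columns) with
#'   one row per subject.  Categorical variables must already be expanded to
#'   indicator columns; [read_analytic_csv()] does this automatically.
#' @param outcome_kind `"continuous"` or `"binary"`.  Defaults to `"binary"`
#'   iff the outcome takes only the values 0 and 1.
#'
#' @return An object of class `analytic_dataset` with fields `y`, `a`, `L`
#'   (numeric matrix), `n` and `outcome_kind`.
#' @export
analytic_dataset <- function(outcome, exposure, covariates,
                             outcome_kind = NULL) {
  y <- as.numeric(outcome)
  a <- as.numeric(exposure)
  L <- as.matrix(covariates)
  storage.mode(L) <- "double"
  rownames(L) <- NULL
  if (is.null(colnames(L))) colnames(L) <- paste0("L", seq_len(ncol(L)))

  n <- length(y)
  if (length(a) != n || nrow(L) != n) {
    stop_dctmle("outcome, exposure and covariates must have the same number of rows",
                "dctmle_data_error")
  }
  if (anyNA(y) || anyNA(a) || anyNA(L)) {
    bad <- which(is.na(y) | is.na(a) | rowSums(is.na(L)) > 0)
    stop_dctmle(sprintf("missing values in rows: %s",
                        paste(utils::head(bad, 10L), collapse = ", ")),
                "dctmle_data_error", rows = bad)
  }
  if (!all(a %in% c(0, 1))) {
    stop_dctmle("exposure must contain only 0 and 1",
                "dctmle_domain_error")
  }
  if (length(unique(a)) < 2L) {
    stop_dctmle("exposure must contain at least one exposed and one unexposed subject",
                "dctmle_domain_error")
  }
  if (is.null(outcome_kind)) {
    outcome_kind <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  outcome_kind <- match.arg(outcome_kind, c("continuous", "binary"))

  structure(list(y = y, a = a, L = L, n = n, outcome_kind = outcome_kind),
            class = "analytic_dataset")
}

#' @export
print.analytic_dataset <- function(x, ...) {
  cat(sprintf("<analytic_dataset>  n = %d, %d covariate column(s), %s outcome\n",
              x$n, ncol(x$L), x$outcome_kind))
  cat(sprintf("  exposed: %d, unexposed: %d\n", sum(x$a == 1), sum(x$a == 0)))
  invisible(x)
}

#' Read an analytic dataset from CSV
#'
#' Reads a rectangular CSV (header row, UTF-8, '.' decimal separator) and
#' returns a validated [analytic_dataset()].  Character or factor covariates
#' are expanded into reference-level-dropped indicator columns *before* any
#' sample splitting, so all cross-fit folds share a single design matrix.
#'
#' @param path Path to the CSV file.
#' @param outcome_col,exposure_col Column names of the outcome and exposure.
#' @param covariate_cols Character vector of covariate column names.
#' @return An [analytic_dataset()].
#' @export
read_analytic_csv <- function(path, outcome_col, exposure_col,
                              covariate_cols) {
  if (!file.exists(path)) {
    stop_dctmle(sprintf("file not found: %s", path), "dctmle_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  wanted <- c(outcome_col, exposure_col, covariate_cols)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols)) {
    stop_dctmle(sprintf("column(s) not found in %s: %s", path,
                        paste(missing_cols, collapse = ", ")),
                "dctmle_column_error")
  }
  df <- df[, wanted, drop = FALSE]
  na_rows <- which(rowSums(is.na(df)) > 0)
  if (length(na_rows)) {
    stop_dctmle(sprintf("missing cells in rows: %s",
                        paste(utils::head(na_rows, 10L), collapse = ", ")),
                "dctmle_data_error", rows = na_rows)
  }

  a_raw <- df[[exposure_col]]
  if (is.logical(a_raw)) a_raw <- as.numeric(a_raw)
  if (is.character(a_raw) && all(a_raw %in% c("0", "1"))) {
    a_raw <- as.numeric(a_raw)
  }
  if (!is.numeric(a_raw) || !all(a_raw %in% c(0, 1))) {
    stop_dctmle(sprintf("exposure column '%s' has values outside {0, 1}",
                        exposure_col), "dctmle_domain_error")
  }

  y <- df[[outcome_col]]
  if (!is.numeric(y)) {
    stop_dctmle(sprintf("outcome column '%s' is not numeric", outcome_col),
                "dctmle_domain_error")
  }

  # reference-level-dropped indicator expansion, once, on the full data
  blocks <- lapply(covariate_cols, function(cn) {
    col <- df[[cn]]
    if (is.numeric(col)) {
      m <- matrix(as.numeric(col), ncol = 1,
                  dimnames = list(NULL, cn))
      return(m)
    }
    f <- factor(col)
    if (nlevels(f) < 2L) {
      m <- matrix(0, nrow = nrow(df), ncol = 1,
                  dimnames = list(NULL, cn))
      return(m)
    }
    mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cn, "_", levels(f)[-1])
    mm
  })
  L <- do.call(cbind, blocks)
  analytic_dataset(y, a_raw, L)
}

#' Outcome scaling metadata
#'
#' Records the observed outcome range used for the min-max transform of a
#' continuous outcome onto \[0, 1\].  The targeting (fluctuation) step works
#' on the unit interval via a logistic link, so continuous outcomes are
#' scaled first and the treatment effect is back-transformed by multiplying
#' with the range.  For a binary outcome the transform is the identity.
#'
#' @param y Outcome vector used to derive the range (ignored when `y_min`
#'   and `y_max` are supplied).
#' @param kind `"continuous"` or `"binary"`.
#' @param y_min,y_max Optional explicit range.
#' @return Object of class `outcome_scale` with fields `y_min`, `y_max`,
#'   `kind`.
#' @export
outcome_scale <- function(y = NULL, kind = c("continuous", "binary"),
                          y_min = NULL, y_max = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    return(structure(list(y_min = 0, y_max = 1, kind = kind),
                     class = "outcome_scale"))
  }
  y_min <- y_min %||% min(y)
  y_max <- y_max %||% max(y)
  if (!is.finite(y_min) || !is.finite(y_max) || y_max <= y_min) {
    stop_dctmle("degenerate outcome: y_max must exceed y_min",
                "dctmle_degenerate_outcome_error")
  }
  structure(list(y_min = y_min, y_max = y_max, kind = kind),
            class = "outcome_scale")
}

#' Min-max scale an outcome onto \[0, 1\]
#'
#' @param y Numeric vector on the original outcome scale.
#' @param scale An [outcome_scale()].
#' @return `(y - y_min) / (y_max - y_min)` for a continuous scale; `y`
#'   unchanged for a binary scale.
#' @export
scale_outcome <- function(y, scale) {
  if (scale$kind == "binary") return(y)
  if (min(y) < scale$y_min - 1e-12 || max(y) > scale$y_max + 1e-12) {
    stop_dctmle("outcome values outside the declared scaling range",
                "dctmle_domain_error")
  }
  (y - scale$y_min) / (scale$y_max - scale$y_min)
}

#' Back-transform scaled predictions to the original outcome scale
#'
#' @param y_star Numeric vector on the \[0, 1\] scale.
#' @param scale An [outcome_scale()].
#' @return `y_star * (y_max - y_min) + y_min` (identity for binary).
#' @export
unscale_outcome <- function(y_star, scale) {
  if (scale$kind == "binary") return(y_star)
  y_star * (scale$y_max - scale$y_min) + scale$y_min
}

#' Back-transform a treatment effect from the scaled to the original scale
#'
#' The additive minimum cancels in the difference of the two counterfactual
#' means, so the effect is rescaled by the outcome range alone.
#'
#' @param ate_star Treatment effect on the \[0, 1\] outcome scale.
#' @param scale An [outcome_scale()].
#' @return `(y_max - y_min) * ate_star` (identity for binary).
#' @export
unscale_ate <- function(ate_star, scale) {
  if (scale$kind == "binary") return(ate_star)
  (scale$y_max - scale$y_min) * ate_star
}

# ---- result container ------------------------------------------------------

new_dc_result <- function(ate, variance, per_repetition, settings,
                          n_failed = 0L) {
  stopifnot(variance >= 0)
  se <- sqrt(variance)
  structure(list(
    ate = ate,
    variance = variance,
    std_error = se,
    ci_lower = ate - 1.96 * se,
    ci_upper = ate + 1.96 * se,
    per_repetition = per_repetition,
    n_failed = as.integer(n_failed),
    settings = settings
  ), class = "dc_result")
}

#' @export
print.dc_result <- function(x, ...) {
  cat(sprintf("ATE %.4g (95%% CI %.4g to %.4g)\n",
              x$ate, x$ci_lower, x$ci_upper))
  cat(sprintf("  std. error %.4g over %d repetition(s) (%d failed), aggregation: %s\n",
              x$std_error, nrow(x$per_repetition), x$n_failed,
              x$settings$aggregation %||% "median"))
  invisible(x)
}

#' Write an estimation result to JSON
#'
#' Serialises a `dc_result` (point estimate, variance, Wald 95% CI, the full
#' per-repetition trace and a settings echo sufficient to reproduce the run)
#' with full numeric precision, so that [read_result_json()] restores every
#' numeric field bit-exactly.
#'
#' @param result A `dc_result` as returned by [run_dc_tmle()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "dc_result"))
  doc <- list(
    ate = result$ate,
    variance = result$variance,
    std_error = result$std_error,
    ci_lower = result$ci_lower,
    ci_upper = result$ci_upper,
    per_repetition = list(
      global_ate = result$per_repetition$global_ate,
      global_variance = result$per_repetition$global_variance
    ),
    n_failed = result$n_failed,
    settings = result$settings,
    package_version = as.character(utils::packageVersion("dctmle"))
  )
  ok <- tryCatch({
    # I(17) significant digits: doubles survive the round trip bit-exactly
    suppressWarnings(jsonlite::write_json(doc, path, auto_unbox = TRUE,
                                          digits = I(17), null = "null"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    stop_dctmle(sprintf("cannot write result to '%s'", path),
                "dctmle_io_error")
  }
  invisible(path)
}

#' Read an estimation result back from JSON
#'
#' @param path Path written by [write_result_json()].
#' @return A `dc_result`.
#' @export
read_result_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- new_dc_result(
    ate = doc$ate,
    variance = doc$variance,
    per_repetition = data.frame(
      global_ate = as.numeric(doc$per_repetition$global_ate),
      global_variance = as.numeric(doc$per_repetition$global_variance)
    ),
    settings = doc$settings,
    n_failed = doc$n_failed
  )
  res
}
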