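# Cross-fitting driver: random partition into S splits, role rotation,
# local -> global -> overall aggregation over k repeated partitions.

#' Run settings for DC-TMLE
#'
#' @param n_split Number of splits S (default 3; each split serves once as
#'   exposure-fitting, outcome-fitting and evaluation fold).
#' @param num_cf Number of repetitions k of the whole split-rotate-estimate
#'   cycle (default 100).
#' @param cv_folds Super-Learner cross-validation folds V (default 10).
#' @param learners_exposure,learners_outcome Learner libraries for the two
#'   nuisance models (names or [learner_spec()] lists); they may differ.
#' @param covars_exposure,covars_outcome Covariate column subsets for the
#'   two nuisance models (default: all columns).
#' @param aggregation `"median"` (default, robust to extreme repetitions)
#'   or `"mean"`.
#' @param seed Master seed; all repetition-level seeds derive from it.
#' @param workers Number of parallel workers for the repetitions.  Results
#'   are invariant to the worker count.
#' @param weighted_fluctuation Use the weighted fluctuation variant.
#' @return A `run_settings` list.
#' @export
run_settings <- function(n_split = 3L, num_cf = 100L, cv_folds = 10L,
                         learners_exposure = c("l1_glm", "random_forest",
                                               "gradient_boosting"),
                         learners_outcome = learners_exposure,
                         covars_exposure = NULL, covars_outcome = NULL,
                         aggregation = c("median", "mean"), seed = 1L,
                         workers = 1L, weighted_fluctuation = FALSE) {
  aggregation <- match.arg(aggregation)
  if (n_split < 3L) {
    stop_dctmle("n_split must be at least 3 (three distinct roles)",
                "dctmle_config_error")
  }
  if (num_cf < 1L || cv_folds < 2L) {
    stop_dctmle("num_cf must be >= 1 and cv_folds >= 2",
                "dctmle_config_error")
  }
  structure(list(
    n_split = as.integer(n_split), num_cf = as.integer(num_cf),
    cv_folds = as.integer(cv_folds),
    learners_exposure = as_learner_specs(learners_exposure),
    learners_outcome = as_learner_specs(learners_outcome),
    covars_exposure = covars_exposure, covars_outcome = covars_outcome,
    aggregation = aggregation, seed = as.integer(seed),
    workers = as.integer(workers),
    weighted_fluctuation = isTRUE(weighted_fluctuation)
  ), class = "run_settings")
}

new_split_assignment <- function(fold_of_row, rotation) {
  structure(list(fold_of_row = fold_of_row, rotation = rotation),
            class = "split_assignment")
}

#' Randomly partition subjects into splits with a role rotation
#'
#' A uniformly random permutation is sliced into S nearly equal folds
#' (sizes differ by at most one).  The rotation assigns, for every
#' evaluation fold s, the exposure model fitted on fold `(s mod S) + 1` and
#' the outcome model fitted on fold `((s + 1) mod S) + 1`; for S = 3 this is
#' the rotation ((1,2,3), (2,3,1), (3,1,2)), and every fold holds every role
#' exactly once.
#'
#' @param n Number of subjects.
#' @param n_split Number of splits S (>= 3).
#' @param seed Integer seed.
#' @return A `split_assignment` with `fold_of_row` (length-n fold labels)
#'   and `rotation` (list of `(eval, exposure, outcome)` triples).
#' @export
make_split_assignment <- function(n, n_split = 3L, seed = 1L) {
  n_split <- as.integer(n_split)
  if (n_split < 3L) {
    stop_dctmle("n_split must be at least 3", "dctmle_config_error")
  }
  if (n < 3L * n_split) {
    stop_dctmle(sprintf("n = %d too small for %d splits", n, n_split),
                "dctmle_sample_size_error")
  }
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_split, n_split) +
    c(rep(1L, n %% n_split), rep(0L, n_split - n %% n_split))
  fold_of_row <- integer(n)
  fold_of_row[perm] <- rep(seq_len(n_split), times = sizes)
  rotation <- lapply(seq_len(n_split), function(s) {
    c(eval = s,
      exposure = (s %% n_split) + 1L,
      outcome = ((s + 1L) %% n_split) + 1L)
  })
  new_split_assignment(fold_of_row, rotation)
}

#' One repetition: split, fit nuisances per fold, rotate, aggregate
#'
#' Fits one exposure Super-Learner and one outcome Super-Learner per fold,
#' then runs the targeting steps for each rotation triple.  The global ATE
#' is the mean of the S local ATEs; the global variance is the mean of the
#' S local EIF variances.
#'
#' @param dataset An [analytic_dataset()].
#' @param config A [run_settings()].
#' @param seed Integer seed for this repetition.
#' @param assignment Optional precomputed `split_assignment` (mainly for
#'   testing); by default a fresh random one is drawn from `seed`.
#' @return List of class `repetition_result`: `global_ate`,
#'   `global_variance`, `split_estimates`.
#' @export
run_one_repetition <- function(dataset, config, seed,
                               assignment = NULL) {
  scale <- dataset_scale(dataset)
  assignment <- assignment %||%
    make_split_assignment(dataset$n, config$n_split, seed)
  S <- length(assignment$rotation)
  covT <- config$covars_exposure %||% colnames(dataset$L)
  covO <- config$covars_outcome %||% colnames(dataset$L)
  y_star <- scale_outcome(dataset$y, scale)
  fit_seeds <- derive_seeds(seed, 2L * S)

  exposure_fits <- vector("list", S)
  outcome_fits <- vector("list", S)
  for (s in seq_len(S)) {
    rows <- which(assignment$fold_of_row == s)
    exposure_fits[[s]] <- fit_superlearner(
      dataset$L[rows, covT, drop = FALSE], dataset$a[rows],
      config$learners_exposure, family = "binomial",
      cv_folds = config$cv_folds, seed = fit_seeds[s])
    outcome_fits[[s]] <- fit_superlearner(
      cbind(A = dataset$a[rows], dataset$L[rows, covO, drop = FALSE]),
      y_star[rows],
      config$learners_outcome,
      family = if (dataset$outcome_kind == "binary") "binomial" else "gaussian",
      cv_folds = config$cv_folds, seed = fit_seeds[S + s])
  }

  split_estimates <- lapply(assignment$rotation, function(tri) {
    run_split_tmle(dataset,
                   eval_rows = which(assignment$fold_of_row == tri[["eval"]]),
                   exposure_model = exposure_fits[[tri[["exposure"]]]],
                   outcome_model = outcome_fits[[tri[["outcome"]]]],
                   scale = scale,
                   covars_exposure = covT, covars_outcome = covO,
                   weighted_fluctuation = config$weighted_fluctuation)
  })
  locals <- vapply(split_estimates, `[[`, numeric(1), "ate_local")
  vars <- vapply(split_estimates, `[[`, numeric(1), "var_local")
  structure(list(global_ate = mean(locals), global_variance = mean(vars),
                 split_estimates = split_estimates),
            class = "repetition_result")
}

dataset_scale <- function(dataset) {
  if (dataset$outcome_kind == "binary") {
    outcome_scale(kind = "binary")
  } else {
    outcome_scale(dataset$y, kind = "continuous")
  }
}

#' Aggregate repetition results into the overall estimate
#'
#' The overall ATE is the median (default) or mean of the k global ATEs.
#' The overall variance is the median (or mean) over repetitions of
#' `global_variance_r + (global_ate_r - overall_ate)^2`, i.e. within-split
#' variance plus between-split variance; the Wald 95% CI uses 1.96 standard
#' errors.
#'
#' @param reps List of `repetition_result` objects.
#' @param method `"median"` or `"mean"`.
#' @param settings Optional settings echo stored in the result.
#' @param n_failed Number of failed (excluded) repetitions.
#' @return A `dc_result`.
#' @export
aggregate_repetitions <- function(reps, method = c("median", "mean"),
                                  settings = NULL, n_failed = 0L) {
  method <- match.arg(method)
  if (!length(reps)) {
    stop_dctmle("no successful repetitions to aggregate",
                "dctmle_estimation_error")
  }
  agg <- if (method == "median") stats::median else mean
  g_ate <- vapply(reps, `[[`, numeric(1), "global_ate")
  g_var <- vapply(reps, `[[`, numeric(1), "global_variance")
  overall_ate <- agg(g_ate)
  overall_var <- agg(g_var + (g_ate - overall_ate)^2)
  new_dc_result(overall_ate, overall_var,
                per_repetition = data.frame(global_ate = g_ate,
                                            global_variance = g_var),
                settings = settings_echo(settings, method),
                n_failed = n_failed)
}

settings_echo <- function(settings, method) {
  if (is.null(settings)) return(list(aggregation = method))
  list(
    n_split = settings$n_split,
    num_cf = settings$num_cf,
    cv_folds = settings$cv_folds,
    learners_exposure = vapply(settings$learners_exposure, `[[`,
                               character(1), "name"),
    learners_outcome = vapply(settings$learners_outcome, `[[`,
                              character(1), "name"),
    covars_exposure = settings$covars_exposure,
    covars_outcome = settings$covars_outcome,
    aggregation = settings$aggregation,
    seed = settings$seed,
    workers = settings$workers,
    weighted_fluctuation = settings$weighted_fluctuation
  )
}

#' Double cross-fit TMLE of the average treatment effect
#'
#' Runs `num_cf` independent repetitions of the split-rotate-estimate cycle
#' (parallelisable over repetitions; the per-repetition seeds are all drawn
#' from the master seed up front, so the result is bit-identical for any
#' worker count) and aggregates them into the overall ATE, its standard
#' error and Wald 95% confidence interval.
#'
#' A repetition whose evaluation split lacks one exposure arm fails and is
#' excluded; more than 20% failed repetitions is treated as a positivity
#' diagnostic and raises an error.
#'
#' @param dataset An [analytic_dataset()].
#' @param config A [run_settings()].
#' @param progress Emit a heartbeat line per repetition (serial runs only).
#' @return A `dc_result`.
#' @export
run_dc_tmle <- function(dataset, config = run_settings(), progress = FALSE) {
  stopifnot(inherits(dataset, "analytic_dataset"))
  k <- config$num_cf
  rep_seeds <- derive_seeds(config$seed, k)
  t0 <- Sys.time()

  fail_record <- function(r) {
    function(e) structure(list(repetition = r, message = conditionMessage(e)),
                          class = "repetition_failure")
  }
  one <- function(r) {
    tryCatch(run_one_repetition(dataset, config, rep_seeds[r]),
             dctmle_degenerate_split_error = fail_record(r),
             dctmle_estimation_error = fail_record(r))
  }
  if (config$workers > 1L) {
    reps <- parallel::mclapply(seq_len(k), one, mc.cores = config$workers,
                               mc.preschedule = TRUE)
  } else {
    reps <- vector("list", k)
    for (r in seq_len(k)) {
      reps[[r]] <- one(r)
      if (progress) {
        message(sprintf("repetition %d/%d done (%.1f s elapsed)", r, k,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      }
    }
  }

  failed <- vapply(reps, inherits, logical(1), "repetition_failure")
  if (any(failed)) {
    if (mean(failed) > 0.2) {
      stop_dctmle(sprintf(
        "%d of %d repetitions failed (degenerate splits); this indicates positivity problems",
        sum(failed), k), "dctmle_estimation_error")
    }
    warning(sprintf("excluded %d failed repetition(s): %s", sum(failed),
                    paste(which(failed), collapse = ", ")), call. = FALSE)
  }
  aggregate_repetitions(reps[!failed], method = config$aggregation,
                        settings = config, n_failed = sum(failed))
}

#' No-split (conventional) TMLE
#'
#' The comparison estimator of the simulation harness: both nuisance
#' Super-Learners are fitted on the full data and the targeting step is
#' evaluated on the same rows (k = 1, no sample splitting).
#'
#' @param dataset An [analytic_dataset()].
#' @param config A [run_settings()]; `n_split` and `num_cf` are ignored.
#' @return A `dc_result` with a single "repetition".
#' @export
run_tmle_nocf <- function(dataset, config = run_settings()) {
  stopifnot(inherits(dataset, "analytic_dataset"))
  scale <- dataset_scale(dataset)
  covT <- config$covars_exposure %||% colnames(dataset$L)
  covO <- config$covars_outcome %||% colnames(dataset$L)
  y_star <- scale_outcome(dataset$y, scale)
  fit_seeds <- derive_seeds(config$seed, 2L)

  exposure_fit <- fit_superlearner(
    dataset$L[, covT, drop = FALSE], dataset$a, config$learners_exposure,
    family = "binomial", cv_folds = config$cv_folds, seed = fit_seeds[1])
  outcome_fit <- fit_superlearner(
    cbind(A = dataset$a, dataset$L[, covO, drop = FALSE]), y_star,
    config$learners_outcome,
    family = if (dataset$outcome_kind == "binary") "binomial" else "gaussian",
    cv_folds = config$cv_folds, seed = fit_seeds[2])

  est <- run_split_tmle(dataset, seq_len(dataset$n), exposure_fit,
                        outcome_fit, scale,
                        covars_exposure = covT, covars_outcome = covO,
                        weighted_fluctuation = config$weighted_fluctuation)
  rep1 <- structure(list(global_ate = est$ate_local,
                         global_variance = est$var_local,
                         split_estimates = list(est)),
                    class = "repetition_result")
  aggregate_repetitions(list(rep1), method = config$aggregation,
                        settings = config)
}
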