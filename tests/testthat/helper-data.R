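# Fixture builders shared across test files.  All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

# Confounded dataset where every nuisance model is exactly linear/logistic,
# so a plain GLM library is correctly specified.
make_linear_dataset <- function(n, seed, theta = 1.5) {
  withr::with_seed(seed, {
    L <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, paste0("X", 1:3)))
    prop <- stats::plogis(0.4 * L[, 1] - 0.5 * L[, 2])
    a <- stats::rbinom(n, 1, prop)
    y <- theta * a + L[, 1] + 0.8 * L[, 2] - 0.5 * L[, 3] + stats::rnorm(n)
    analytic_dataset(y, a, L)
  })
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

glm_only <- list(learner_spec("glm"))

fast_settings <- function(...) {
  run_settings(num_cf = 2L, cv_folds = 3L, learners_exposure = glm_only,
               seed = 1L, ...)
}
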