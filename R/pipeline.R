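#' Run the full social-structure pipeline on one population
#'
#' Chains the stages: association matrix and summary -> permutation tests
#' (CV of indices, gregariousness, dyadic preference/avoidance) -> network
#' metrics with bootstrap SEs -> lagged association rates (both scales,
#' jackknifed) -> model fitting and QAIC selection. Artifacts are written
#' as plain CSV/JSON files under `output_dir`, each carrying a provenance
#' comment (package version and seed).
#'
#' @param obs an [observation_set()] (e.g. read with [read_observations()]
#'   or produced by a generator)
#' @param output_dir directory for artifact files (created if missing);
#'   NULL skips writing
#' @param seed integer seed governing every stochastic stage
#' @param n_permutations,flips_per_permutation permutation test effort
#' @param n_boot bootstrap replicates for network SEs
#' @param n_starts optimiser restarts per candidate model
#' @return list with components `summary`, `cv_test`, `greg_test`,
#'   `dyadic`, `metrics`, `lar_minute`, `lar_day`, `selection`,
#'   `linear_day_fit`
#' @export
run_pipeline <- function(obs, output_dir = NULL, seed = 1,
                         n_permutations = 1000, flips_per_permutation = 500,
                         n_boot = 200, n_starts = 20) {
  cfg <- permutation_config(n_permutations, flips_per_permutation,
                            seed = seed)
  summary <- association_summary(obs)
  cv_test <- permutation_test_cv(obs, cfg)
  greg_test <- permutation_test_gregariousness(obs, cfg)
  dyadic <- dyadic_significance(obs, cfg)
  metrics <- bootstrap_network_ses(obs, n_boot = n_boot, seed = seed)
  lar_minute <- lar_jackknife(obs, "minute", "five_minutes")
  lar_day <- tryCatch(lar_jackknife(obs, "day", "one_day"),
                      error = function(e) NULL)
  set.seed(seed)
  selection <- select_lar_model(lar_minute, n_starts = n_starts)
  linear_day_fit <- if (!is.null(lar_day) && sum(lar_day$den > 0) >= 2) {
    fit_lar_model(lar_day, "linear", n_starts = n_starts)
  } else NULL
  out <- list(summary = summary, cv_test = cv_test, greg_test = greg_test,
              dyadic = dyadic, metrics = metrics, lar_minute = lar_minute,
              lar_day = lar_day, selection = selection,
              linear_day_fit = linear_day_fit)
  if (!is.null(output_dir)) .write_pipeline_artifacts(out, obs, output_dir, seed)
  out
}

.provenance <- function(seed) {
  sprintf("# fissionet %s | seed %s | %s",
          as.character(utils::packageVersion("fissionet")), seed,
          format(Sys.time(), "%Y-%m-%d"))
}

.write_pipeline_artifacts <- function(res, obs, dir, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- .provenance(seed)
  wcsv <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
  }
  write_observations(obs, file.path(dir, "observations.csv"))
  am <- association_matrix(obs)
  utils::write.csv(round(am$AI, 6), file.path(dir, "association_matrix.csv"))
  metrics_df <- data.frame(
    measure = names(res$metrics$means),
    mean = as.numeric(res$metrics$means),
    se = as.numeric(res$metrics$se[names(res$metrics$means)]))
  wcsv(metrics_df, "network_metrics.csv")
  wcsv(as.data.frame(res$lar_minute), "lar_minute.csv")
  if (!is.null(res$lar_day)) wcsv(as.data.frame(res$lar_day), "lar_day.csv")
  wcsv(res$selection$table, "model_selection.csv")
  wcsv(res$dyadic$dyads, "dyadic_significance.csv")
  tests <- data.frame(
    statistic = c(res$cv_test$statistic_name, res$greg_test$statistic_name),
    observed = c(res$cv_test$observed, res$greg_test$observed),
    null_mean = c(res$cv_test$null_mean, res$greg_test$null_mean),
    p_high = c(res$cv_test$p_high, res$greg_test$p_high),
    p_low = c(res$cv_test$p_low, res$greg_test$p_low))
  wcsv(tests, "permutation_tests.csv")
  invisible(dir)
}
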