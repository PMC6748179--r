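#' Run the full simulate - features - train - report pipeline
#'
#' Chains the whole framework with one call: simulate a cohort, extract the
#' feature table, score the questionnaires, train the six estimators and
#' summarise the prediction errors. Intended both for interactive use and
#' as the backend of the shipped command-line wrapper
#' (`system.file("scripts", "usability-eval.R", package = "iseval")`).
#'
#' @param config Named list overriding defaults: any argument of
#'   [simulate_cohort()] plus `grid` (`"demo"` or `"default"`), `folds`,
#'   and `out_dir` (when set, the feature CSV, manifest, error table and
#'   resolved config JSON are written there).
#' @param seed Master seed for the cohort, split and search.
#' @return List with `cohort`, `features`, `model`, `errors` and
#'   `portfolios` (per prototype).
#' @export
run_pipeline <- function(config = list(), seed = 1L) {
  sim_args <- config[intersect(names(config), names(formals(simulate_cohort)))]
  sim_args$seed <- seed
  cohort <- do.call(simulate_cohort, sim_args)
  features <- log_feature_table(cohort)
  grid <- switch(config$grid %||% "demo",
                 demo = demo_gbrf_grid(), default = default_gbrf_grid())
  model <- train_usability_model(features, cohort$manifest, grid = grid,
                                 folds = config$folds %||% 8L, seed = seed)
  errors <- evaluate_errors(model)
  portfolios <- lapply(split(cohort$manifest, cohort$manifest$prototype),
                       portfolio)
  out <- list(cohort = cohort, features = features, model = model,
              errors = errors, portfolios = portfolios)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(config$out_dir, "features.csv"))
    write.csv(cohort$manifest[, setdiff(names(cohort$manifest), "log")],
              file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(errors, file.path(config$out_dir, "errors.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, grid = config$grid %||% "demo",
           folds = config$folds %||% 8L,
           cohort = sim_args[setdiff(names(sim_args), "policy_sampler")]),
      file.path(config$out_dir, "run-config.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}
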