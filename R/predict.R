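#' Hyperparameter grids for the boosted-regression estimators
#'
#' `default_gbrf_grid()` is the full exhaustive search space: five axes
#' (boosting stages, learning rate, maximum tree depth, subsample fraction,
#' minimum leaf size) with 8 x 8 x 8 x 8 x 5 = 20,480 combinations.
#' `demo_gbrf_grid()` is a small 128-combination grid with the same axes,
#' sized so that a full six-label search with eightfold cross-validation
#' runs in minutes on one CPU.
#'
#' @return A tibble with columns `n_trees`, `learning_rate`, `max_depth`,
#'   `subsample`, `min_leaf`.
#' @name gbrf_grids
NULL

#' @rdname gbrf_grids
#' @export
default_gbrf_grid <- function() {
  tidyr::expand_grid(
    n_trees = c(25, 50, 75, 100, 150, 200, 300, 400),
    learning_rate = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3),
    max_depth = 1:8,
    subsample = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1.0),
    min_leaf = c(1, 2, 3, 5, 8)
  )
}

#' @rdname gbrf_grids
#' @export
demo_gbrf_grid <- function() {
  tidyr::expand_grid(
    n_trees = c(15, 30, 60, 120),
    learning_rate = c(0.05, 0.1, 0.2, 0.3),
    max_depth = 1:4,
    subsample = c(0.7, 1.0),
    min_leaf = 1
  )
}

# pseudo-Huber deviance (slope 1), matching the boosting objective
pseudo_huber <- function(residual, delta = 1) {
  delta^2 * (sqrt(1 + (residual / delta)^2) - 1)
}

gbrf_params <- function(config, seed) {
  list(objective = "reg:pseudohubererror", eta = config$learning_rate,
       max_depth = config$max_depth, subsample = config$subsample,
       min_child_weight = config$min_leaf, tree_method = "exact",
       nthread = 1, verbosity = 0, seed = seed)
}

# labels are standardised before boosting: the pseudo-Huber hessian decays
# as |r|^-3, so residuals on the raw questionnaire scale (tens of SUS
# points) would make the Newton leaf updates explode
standardise_label <- function(y) {
  s <- sd(y)
  list(center = mean(y), scale = if (is.finite(s) && s > 0) s else 1)
}

fit_gbrf <- function(x, y, config, seed = 1L, nrounds = config$n_trees) {
  std <- standardise_label(y)
  d <- xgboost::xgb.DMatrix(as.matrix(x),
                            label = (y - std$center) / std$scale,
                            nthread = 1)
  booster <- xgboost::xgb.train(params = gbrf_params(config, seed), data = d,
                                nrounds = nrounds)
  structure(list(booster = booster, center = std$center, scale = std$scale),
            class = "gbrf_fit")
}

#' @export
predict.gbrf_fit <- function(object, newdata, ...) {
  predict(object$booster, as.matrix(newdata), ...) * object$scale +
    object$center
}

#' Split samples into training and test partitions
#'
#' Reproducible random split in a 4:1 ratio (test size `round(n / 5)`), no
#' sample in both parts.
#'
#' @param n Number of samples (or a data frame, whose rows are counted).
#' @param ratio Train:test ratio as `c(train, test)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, ratio = c(4, 1), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 10) stop("need at least 10 samples to split", call. = FALSE)
  n_test <- round(n * ratio[2] / sum(ratio))
  withr::with_seed(as.integer(seed), {
    test <- sort(sample.int(n, n_test))
  })
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Fits a gradient-boosted regression forest with pseudo-Huber loss for
#' every hyperparameter combination and ranks the combinations by mean
#' held-out deviance over the folds (ascending). Combinations that differ
#' only in the number of boosting stages share one training pass per fold:
#' the model is trained to the largest stage count and scored at every
#' intermediate cut.
#'
#' @param x Data frame or matrix of feature columns (training samples).
#' @param y Numeric label vector.
#' @param grid Hyperparameter grid, see [default_gbrf_grid()].
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and subsampling.
#' @return A `gbrf_grid_search` object: the ranked `results` tibble (grid
#'   columns + `cv_loss` + `rank`) plus the data and fold assignment.
#' @export
grid_search <- function(x, y, grid = demo_gbrf_grid(), folds = 8L,
                        seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(grid) >= 1, folds >= 2, nrow(x) == length(y),
            nrow(x) >= folds)
  withr::with_seed(as.integer(seed), {
    fold_id <- sample(rep(seq_len(folds), length.out = nrow(x)))
  })
  std <- standardise_label(y)
  ys <- (y - std$center) / std$scale
  axes <- setdiff(names(grid), "n_trees")
  groups <- dplyr::group_split(dplyr::group_by(grid, dplyr::across(
    dplyr::all_of(axes))))
  dtrains <- lapply(seq_len(folds), function(k) {
    xgboost::xgb.DMatrix(x[fold_id != k, , drop = FALSE],
                         label = ys[fold_id != k], nthread = 1)
  })
  res <- lapply(groups, function(g) {
    cuts <- sort(unique(g$n_trees))
    loss <- matrix(0, length(cuts), folds)
    for (k in seq_len(folds)) {
      held <- fold_id == k
      fit <- xgboost::xgb.train(
        params = gbrf_params(g[1, ], seed), data = dtrains[[k]],
        nrounds = max(cuts)
      )
      for (ci in seq_along(cuts)) {
        pred <- predict(fit, x[held, , drop = FALSE],
                        iterationrange = c(1, cuts[ci]))
        loss[ci, k] <- sum(pseudo_huber(pred - ys[held]))
      }
    }
    out <- g[match(cuts, g$n_trees), , drop = FALSE]
    out$cv_loss <- rowSums(loss) / nrow(x)
    out
  })
  results <- dplyr::arrange(dplyr::bind_rows(res), .data$cv_loss)
  results$rank <- seq_len(nrow(results))
  structure(
    list(results = results, x = x, y = y, fold_id = fold_id, seed = seed,
         feature_names = colnames(x)),
    class = "gbrf_grid_search"
  )
}

#' @export
print.gbrf_grid_search <- function(x, ...) {
  best <- x$results[1, ]
  cat(sprintf(
    "<gbrf_grid_search> %d configurations, %d samples x %d features; best CV deviance %.4f\n",
    nrow(x$results), nrow(x$x), ncol(x$x), best$cv_loss
  ))
  invisible(x)
}

#' Deviance-weighted feature importance voting
#'
#' Aggregates per-estimator feature importances into one ranking, each
#' estimator's vote weighted by the reciprocal of its cross-validation
#' deviance, so better estimators count more. With identical deviances the
#' vote reduces to the plain mean importance.
#'
#' @param importances List of named importance vectors (one per estimator;
#'   features missing from a vector count as 0).
#' @param losses Numeric vector of the estimators' deviances.
#' @param feature_names All candidate feature names.
#' @return Tibble `feature`, `votes`, sorted descending.
#' @export
importance_vote <- function(importances, losses, feature_names) {
  stopifnot(length(importances) == length(losses))
  w <- 1 / pmax(losses, 1e-12)
  votes <- setNames(numeric(length(feature_names)), feature_names)
  for (k in seq_along(importances)) {
    imp <- importances[[k]]
    votes[names(imp)] <- votes[names(imp)] + w[k] * imp
  }
  out <- tibble::tibble(feature = feature_names, votes = unname(votes))
  dplyr::arrange(out, dplyr::desc(.data$votes))
}

#' Two-stage feature selection for SUS prediction
#'
#' After the initial grid search, the top 1% of estimators by mean
#' cross-validation deviance (205 of the default 20,480-combination grid)
#' are refitted on the training data and their feature importances pooled
#' by 1/deviance-weighted voting — a more robust ranking than trusting a
#' single trained model. The `n_features` highest-voted features are kept
#' and a second grid search over the same grid is run on those columns
#' only.
#'
#' @param search A `gbrf_grid_search` from the initial search.
#' @param n_features Number of features to retain (25).
#' @param n_estimators Number of voting estimators; defaults to
#'   `ceiling(0.01 * combinations)`. If fewer combinations exist than
#'   requested, all are used and the result is flagged.
#' @param rerun_grid Grid for the second search; defaults to the ranked
#'   grid of the initial search.
#' @param folds Folds of the second search.
#' @return List with `features` (selected names), `votes`, `n_estimators`,
#'   `flagged` and `second_search`.
#' @export
sus_feature_selection <- function(search, n_features = 25L,
                                  n_estimators = NULL, rerun_grid = NULL,
                                  folds = 8L) {
  stopifnot(inherits(search, "gbrf_grid_search"))
  ranked <- search$results
  if (is.null(n_estimators)) n_estimators <- ceiling(0.01 * nrow(ranked))
  flagged <- n_estimators > nrow(ranked)
  n_use <- min(n_estimators, nrow(ranked))
  top <- ranked[seq_len(n_use), ]
  importances <- lapply(seq_len(n_use), function(k) {
    fit <- fit_gbrf(search$x, search$y, top[k, ], seed = search$seed)
    imp <- xgboost::xgb.importance(model = fit$booster)
    setNames(imp$Gain, imp$Feature)
  })
  votes <- importance_vote(importances, top$cv_loss, search$feature_names)
  n_keep <- min(n_features, sum(votes$votes > 0))
  features <- votes$feature[seq_len(n_keep)]
  if (is.null(rerun_grid)) {
    rerun_grid <- ranked[, setdiff(names(ranked), c("cv_loss", "rank"))]
  }
  second <- grid_search(search$x[, features, drop = FALSE], search$y,
                        grid = rerun_grid, folds = folds,
                        seed = search$seed)
  list(features = features, votes = votes, n_estimators = n_use,
       flagged = flagged, second_search = second)
}

label_range <- function(label) {
  if (label == "SUS") c(0, 100) else c(1, 7)
}

usability_labels <- c("ATT", "HQ", "HQ-I", "HQ-S", "PQ", "SUS")

#' Train the six questionnaire-score estimators
#'
#' Joins a feature table with per-sample questionnaire scores, splits the
#' samples 4:1 into training and test partitions, and for each of the six
#' labels (SUS, PQ, ATT, HQ-I, HQ-S, HQ) runs the cross-validated grid
#' search and fits the best combination on the full training partition.
#' For SUS, the two-stage importance-voting feature selection is applied
#' and the final model uses only the selected columns.
#'
#' @param features Result of [log_feature_table()] (or a list with `table`
#'   and `registry`).
#' @param labels Data frame with `sample_id` and the six score columns
#'   (e.g. the cohort `manifest`).
#' @param grid Hyperparameter grid.
#' @param folds Cross-validation folds.
#' @param seed Integer seed (split, folds, subsampling).
#' @param sus_selection Apply the SUS feature-selection stage.
#' @param fit_labels Labels to fit (defaults to all six).
#' @return A `usability_model` with one fitted estimator per label and the
#'   stored test partition.
#' @export
train_usability_model <- function(features, labels, grid = demo_gbrf_grid(),
                                  folds = 8L, seed = 1L,
                                  sus_selection = TRUE,
                                  fit_labels = usability_labels) {
  table <- features$table
  registry <- features$registry
  stopifnot(!is.null(table), !is.null(registry),
            all(c("sample_id", fit_labels) %in%
                  c(names(labels), "sample_id")))
  joined <- dplyr::inner_join(table, labels[, c("sample_id", fit_labels)],
                              by = "sample_id")
  feat_cols <- registry$name
  split <- split_train_test(nrow(joined), seed = seed)
  x_train <- joined[split$train, feat_cols]
  x_test <- joined[split$test, feat_cols]
  estimators <- lapply(fit_labels, function(lab) {
    y_train <- joined[[lab]][split$train]
    search <- grid_search(x_train, y_train, grid = grid, folds = folds,
                          seed = seed)
    selection <- NULL
    used <- feat_cols
    if (lab == "SUS" && sus_selection) {
      selection <- sus_feature_selection(search, folds = folds)
      used <- selection$features
      search <- selection$second_search
    }
    best <- search$results[1, ]
    model <- fit_gbrf(joined[split$train, used], y_train, best, seed = seed)
    list(label = lab, model = model, best = best, cv_loss = best$cv_loss,
         features = used, selection = selection)
  })
  names(estimators) <- fit_labels
  structure(
    list(estimators = estimators, feature_names = feat_cols,
         split = split, data = joined, labels = fit_labels, seed = seed,
         grid_size = nrow(grid)),
    class = "usability_model"
  )
}

#' Predict questionnaire scores from log features
#'
#' @param model A `usability_model`.
#' @param features Feature table (rows to predict; must contain the
#'   training feature columns). Defaults to the model's stored test
#'   partition.
#' @return Tibble with `sample_id` (when present) and one range-clipped
#'   column per fitted label (SUS clipped to `[0, 100]`, AttrakDiff-2
#'   scores to `[1, 7]`).
#' @export
predict_scores <- function(model, features = NULL) {
  stopifnot(inherits(model, "usability_model"))
  if (is.null(features)) {
    features <- model$data[model$split$test, ]
  }
  if (is.list(features) && !is.data.frame(features)) features <- features$table
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks training columns, e.g. ", missing_cols[1],
         call. = FALSE)
  }
  out <- if ("sample_id" %in% names(features)) {
    tibble::tibble(sample_id = features$sample_id)
  } else {
    tibble::tibble(.rows = nrow(features))
  }
  for (lab in model$labels) {
    est <- model$estimators[[lab]]
    p <- predict(est$model, as.matrix(features[, est$features]))
    rng <- label_range(lab)
    out[[lab]] <- pmin(pmax(p, rng[1]), rng[2])
  }
  out
}

#' Relative prediction errors on the test partition
#'
#' Per label, the relative absolute error `|yhat - y| / y` of every test
#' sample, summarised by mean, median and standard deviation (in percent).
#' Samples with a zero true score are excluded and flagged.
#'
#' @param model A `usability_model`.
#' @param features,labels Optional feature table and label data frame;
#'   default to the model's stored test partition.
#' @return Tibble with columns `label`, `mean`, `median`, `std`, `n`
#'   (percent errors), attribute `"excluded"` counting dropped samples.
#' @export
evaluate_errors <- function(model, features = NULL, labels = NULL) {
  stopifnot(inherits(model, "usability_model"))
  if (is.null(features)) features <- model$data[model$split$test, ]
  if (is.list(features) && !is.data.frame(features)) features <- features$table
  if (is.null(labels)) labels <- features
  pred <- predict_scores(model, features)
  excluded <- 0L
  rows <- lapply(model$labels, function(lab) {
    y <- labels[[lab]]
    keep <- y != 0
    excluded <<- excluded + sum(!keep)
    rel <- abs(pred[[lab]][keep] - y[keep]) / y[keep] * 100
    tibble::tibble(label = lab, mean = mean(rel), median = median(rel),
                   std = sd(rel), n = sum(keep))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$label)
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.usability_model <- function(x, ...) {
  cat(sprintf("<usability_model> %d estimators over %d features (%d train / %d test samples)\n",
              length(x$estimators), length(x$feature_names),
              length(x$split$train), length(x$split$test)))
  invisible(x)
}

#' Tidy summaries of a fitted usability model
#'
#' `tidy()` returns one row per label with the selected hyperparameters
#' and cross-validation deviance; `glance()` a one-row model summary.
#'
#' @param x A `usability_model`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.usability_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$estimators, function(e) {
    dplyr::bind_cols(tibble::tibble(label = e$label),
                     e$best[, setdiff(names(e$best), "rank")],
                     tibble::tibble(n_features = length(e$features)))
  }))
}

#' @rdname tidy.usability_model
#' @export
glance.usability_model <- function(x, ...) {
  tibble::tibble(
    n_labels = length(x$estimators),
    n_features = length(x$feature_names),
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    grid_size = x$grid_size,
    mean_cv_loss = mean(vapply(x$estimators, function(e) e$cv_loss,
                               numeric(1)))
  )
}

#' @export
generics::tidy

#' @export
generics::glance
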