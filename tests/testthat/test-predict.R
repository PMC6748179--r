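# small synthetic regression problem with two informative features among
# distractors, named like real feature columns
toy_regression <- function(n = 40, p = 12, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- c("Mean(Dice)", "Mean(Sum_itime)",
                     paste0("PCA_VAL_", seq_len(p - 2)))
    y <- 50 + 20 * x[, 1] - 10 * x[, 2] + rnorm(n, 0, 0.5)
    list(x = x, y = y)
  })
}

test_that("train/test split is a reproducible 4:1 partition", {
  s <- split_train_test(31, seed = 3)
  expect_equal(length(s$train), 25)
  expect_equal(length(s$test), 6)
  expect_identical(s, split_train_test(31, seed = 3))
  expect_false(identical(s, split_train_test(31, seed = 4)))
  expect_setequal(c(s$train, s$test), 1:31)
  expect_length(intersect(s$train, s$test), 0)
  expect_error(split_train_test(8), "at least 10")
})

test_that("the hyperparameter grids have the documented sizes", {
  expect_equal(nrow(default_gbrf_grid()), 20480)
  expect_equal(nrow(dplyr::distinct(default_gbrf_grid())), 20480)
  expect_equal(nrow(demo_gbrf_grid()), 128)
})

test_that("grid search ranks configurations by cross-validated deviance", {
  toy <- toy_regression()
  grid <- demo_gbrf_grid()[c(1, 40, 90, 128), ]
  s <- grid_search(toy$x, toy$y, grid = grid, folds = 4, seed = 7)
  expect_equal(nrow(s$results), 4)
  expect_equal(s$results$rank, 1:4)
  expect_true(all(diff(s$results$cv_loss) >= 0))
  # a singleton grid trivially ranks first
  one <- grid_search(toy$x, toy$y, grid = demo_gbrf_grid()[5, ],
                     folds = 4, seed = 7)
  expect_equal(nrow(one$results), 1)
  expect_equal(one$results$rank, 1)
})

test_that("grid search is deterministic given its seed", {
  toy <- toy_regression()
  grid <- demo_gbrf_grid()[c(10, 70), ]
  a <- grid_search(toy$x, toy$y, grid = grid, folds = 4, seed = 9)
  set.seed(12345)  # stray global RNG state must not leak in
  b <- grid_search(toy$x, toy$y, grid = grid, folds = 4, seed = 9)
  expect_equal(a$results, b$results)
})

test_that("staged evaluation equals separately trained stage counts", {
  # the shared-training-pass optimisation must not change the ranking
  toy <- toy_regression(n = 32, p = 6)
  grid2 <- tibble::tibble(n_trees = c(10, 40), learning_rate = 0.1,
                          max_depth = 2, subsample = 1, min_leaf = 1)
  joint <- grid_search(toy$x, toy$y, grid = grid2, folds = 4, seed = 5)
  sep <- lapply(c(10, 40), function(nt) {
    grid_search(toy$x, toy$y, grid = dplyr::mutate(grid2[1, ], n_trees = nt),
                folds = 4, seed = 5)$results$cv_loss
  })
  expect_equal(sort(joint$results$cv_loss), sort(unlist(sep)))
})

test_that("importance voting with equal losses is the plain mean", {
  imps <- list(c(a = 0.5, b = 0.3), c(a = 0.1, c = 0.9), c(b = 0.2, c = 0.4))
  votes <- importance_vote(imps, losses = c(2, 2, 2), c("a", "b", "c", "d"))
  direct <- c(a = 0.6 / 2, b = 0.5 / 2, c = 1.3 / 2, d = 0)
  got <- setNames(votes$votes, votes$feature)
  expect_equal(got[order(names(got))], direct[order(names(direct))])
  # lower loss weighs more
  w <- importance_vote(imps, losses = c(0.1, 10, 10), c("a", "b", "c", "d"))
  expect_equal(w$feature[1], "a")
})

test_that("feature selection keeps 25 columns and flags small grids", {
  toy <- toy_regression(n = 45, p = 30, seed = 3)
  s <- grid_search(toy$x, toy$y, grid = demo_gbrf_grid()[seq(1, 128, 8), ],
                   folds = 4, seed = 11)
  sel <- sus_feature_selection(s, rerun_grid = s$results[1, 1:5],
                               folds = 4)
  expect_equal(sel$n_estimators, ceiling(0.01 * 16))
  expect_false(sel$flagged)
  expect_lte(length(sel$features), 25)
  expect_true("Mean(Dice)" %in% sel$features)
  # asking for more voters than configurations uses all of them, flagged
  sel2 <- sus_feature_selection(s, n_estimators = 205,
                                rerun_grid = s$results[1, 1:5], folds = 4)
  expect_true(sel2$flagged)
  expect_equal(sel2$n_estimators, 16)
})

test_that("fitted predictions stay in range and fit constants exactly", {
  toy <- toy_regression(n = 30, p = 5)
  cfg <- tibble::tibble(n_trees = 30, learning_rate = 0.2, max_depth = 2,
                        subsample = 1, min_leaf = 1)
  const <- iseval:::fit_gbrf(toy$x, rep(62.5, 30), cfg)
  expect_equal(predict(const, toy$x), rep(62.5, 30), tolerance = 1e-6)
})

test_that("adding pure-noise columns does not hurt the training fit", {
  toy <- toy_regression(n = 36, p = 6, seed = 5)
  cfg <- tibble::tibble(n_trees = 60, learning_rate = 0.2, max_depth = 3,
                        subsample = 1, min_leaf = 1)
  base_fit <- iseval:::fit_gbrf(toy$x, toy$y, cfg)
  noise <- matrix(rnorm(36 * 6), 36, 6,
                  dimnames = list(NULL, paste0("noise_", 1:6)))
  aug_fit <- iseval:::fit_gbrf(cbind(toy$x, noise), toy$y, cfg)
  loss <- function(fit, x) {
    sum(iseval:::pseudo_huber(predict(fit, x) - toy$y))
  }
  expect_lte(loss(aug_fit, cbind(toy$x, noise)),
             loss(base_fit, toy$x) * 1.05)
})

test_that("the full model pipeline predicts, clips and reports six labels", {
  co <- cohort31()
  ft <- features31()
  grid <- demo_gbrf_grid()[c(16, 112), ]
  m <- train_usability_model(ft, co$manifest, grid = grid, folds = 4,
                             seed = 6, sus_selection = FALSE)
  expect_s3_class(m, "usability_model")
  pred <- predict_scores(m)
  expect_equal(nrow(pred), length(m$split$test))
  expect_true(all(pred$SUS >= 0 & pred$SUS <= 100))
  for (lab in c("PQ", "ATT", "HQ-I", "HQ-S", "HQ")) {
    expect_true(all(pred[[lab]] >= 1 & pred[[lab]] <= 7))
  }
  err <- evaluate_errors(m)
  expect_equal(err$label, sort(c("ATT", "HQ", "HQ-I", "HQ-S", "PQ", "SUS")))
  expect_true(all(err$n == length(m$split$test)))
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_true(all(c("label", "n_trees", "cv_loss") %in% names(td)))
  expect_equal(glance(m)$n_labels, 6)
  expect_error(predict_scores(m, ft$table[, 1:10]), "lacks")
})

test_that("relative errors follow the hand arithmetic", {
  co <- cohort31()
  ft <- features31()
  m <- train_usability_model(ft, co$manifest,
                             grid = demo_gbrf_grid()[16, ], folds = 4,
                             seed = 8, sus_selection = FALSE,
                             fit_labels = "SUS")
  pred <- predict_scores(m)
  truth <- m$data$SUS[m$split$test]
  expected <- median(abs(pred$SUS - truth) / truth) * 100
  err <- evaluate_errors(m)
  expect_equal(err$median[err$label == "SUS"], expected)
  # a single prediction of 45 against a truth of 50 errs by 10%
  expect_equal(abs(45 - 50) / 50 * 100, 10)
})

test_that("selected features mix quality and effort signals across seeds", {
  ft <- features200()
  co <- cohort200()
  joined <- dplyr::inner_join(ft$table, co$manifest[, c("sample_id", "SUS")],
                              by = "sample_id")
  hits <- 0
  for (s in 1:5) {
    split <- split_train_test(nrow(joined), seed = s)
    search <- grid_search(joined[split$train, ft$registry$name],
                          joined$SUS[split$train],
                          grid = demo_gbrf_grid(), folds = 8, seed = s)
    sel <- sus_feature_selection(search,
                                 rerun_grid = search$results[1, 1:5],
                                 folds = 4)
    quality <- grepl("Dice|Jaccard|Rand|ROC|RAVD|MSE|LOG|OBJ", sel$features)
    effort <- grepl("time", sel$features)
    hits <- hits + (any(quality) && any(effort))
  }
  expect_gte(hits / 5, 0.8)
})
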