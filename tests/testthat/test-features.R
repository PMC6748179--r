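# a minimal hand-built log: five scribble interactions, one undo, known
# times, perfect final segmentation
fixed_log <- function() {
  fix <- two_region_fixture(12, 12)
  seeds <- dplyr::bind_rows(
    border_background_seeds(fix$image, 4),
    seed_points(c(5, 6), c(5, 6), "foreground", n = 1)
  )
  events <- dplyr::bind_rows(
    test_event(1, "add_scribble", 2, 1, 0.5, 0.4,
               list(seeds = seed_points(5, 5, "foreground", n = 1))),
    test_event(2, "add_scribble", 4, 1, 0.5, 0.6,
               list(seeds = seed_points(6, 6, "foreground", n = 2))),
    test_event(2, "undo", 5, 0.5, 0, 0.4, NULL),
    test_event(3, "add_scribble", 7, 1, 0.5, 0.7,
               list(seeds = seed_points(6, 5, "foreground", n = 3))),
    test_event(4, "add_scribble", 9, 1, 0.5, 0.8,
               list(seeds = seed_points(5, 6, "foreground", n = 4))),
    test_event(5, "add_scribble", 12, 1, 0.5, 1.0,
               list(seeds = seed_points(7, 7, "foreground", n = 5))),
    test_event(5, "finish", 13, 0.5, 0, NA, NULL)
  )
  make_test_log(events, seeds, fix$image, fix$mask)
}

test_that("per-segmentation features count events and times exactly", {
  f <- per_segmentation_features(fixed_log())
  expect_equal(ncol(f), 22)
  expect_equal(f[["#Interactions"]], 5)
  expect_equal(f[["#Undos"]], 1)
  expect_equal(f[["#FG_seeds"]], 2)
  expect_equal(f[["#BG_seeds"]], 0)
  expect_equal(f[["#Toggles"]], 0)
  expect_equal(f[["Sum_ctime"]], 2.5)
  expect_equal(f[["Sum_itime"]], 6)
  expect_equal(f[["Sum_wtime"]], 13 - 2)  # last minus first wall clock
  expect_equal(f[["Med_ctime"]], 0.5)
  expect_equal(f[["Dice_AUC"]], mean(c(0.4, 0.6, 0.4, 0.7, 0.8, 1.0)))
})

test_that("a perfect final mask yields the identity metric values", {
  fix <- two_region_fixture(12, 12)
  log <- run_semi_manual(fix$image, fix$mask,
                         robot_policy(jitter_sd = 0, mislabel_prob = 0,
                                      undo_prob = 0, budget = 30,
                                      stop_dice = 1, seed = 1))
  f <- per_segmentation_features(log)
  expect_equal(f$Dice, 1)
  expect_equal(f$RAVD, 0)
  expect_equal(f$MSE, 0)
  expect_equal(f$OBJ_TPR, 1)
})

test_that("base features aggregate the per-segmentation catalogue", {
  logs <- list(fixed_log(), fixed_log())
  b <- base_features(logs)
  expect_equal(ncol(b), 48)
  # aggregating identical logs: mean and median equal the constant
  f <- per_segmentation_features(fixed_log())
  expect_equal(b[["Mean(Dice)"]], f$Dice)
  expect_equal(b[["Med(Dice)"]], f$Dice)
  expect_equal(b[["Mean(#Undos)"]], 1)
})

test_that("seed position features are relative and degenerate to the centre", {
  fix <- two_region_fixture(13, 13)
  seeds <- dplyr::bind_rows(
    border_background_seeds(fix$image, 4),
    seed_points(c(6, 6), c(6, 6), "foreground", n = 1)  # exact centre
  )
  ev <- test_event(1, "add_scribble", 1, 1, 0.1, 0.5,
                   list(seeds = seed_points(6, 6, "foreground", n = 1)))
  log <- make_test_log(ev, seeds, fix$image, fix$mask)
  b <- base_features(list(log))
  expect_equal(b[["Med(Relative_Seed_Coord_H)"]], 0.5)
  expect_equal(b[["Med(Relative_Seed_Coord_V)"]], 0.5)
  expect_equal(b[["Std(Relative_Seed_Coord_H)"]], 0)
  expect_equal(b[["Std(Relative_Seed_Coord_V)"]], 0)
})

test_that("the composite catalogue has exactly the documented columns", {
  b <- base_features(list(fixed_log()))
  comp <- composite_features(b)
  registry <- attr(comp, "registry")
  expect_equal(nrow(registry), 216)
  expect_equal(sum(registry$provenance == "base"), 48)
  expect_equal(sum(registry$provenance == "ratio"), 156)
  expect_equal(sum(registry$provenance == "time_relation"), 12)
  expect_true("Mean(Dice)/Mean(Sum_wtime)" %in% registry$name)
  expect_false(any(duplicated(registry$name)))
  expect_true(all(registry$name %in% names(comp)))
})

test_that("doubling the time totals halves every time-ratio feature", {
  b <- base_features(list(fixed_log()))
  b2 <- b
  for (ts in iseval:::time_summaries) b2[[ts]] <- 2 * b[[ts]]
  c1 <- composite_features(b)
  c2 <- composite_features(b2)
  registry <- attr(c1, "registry")
  ratios <- registry$name[registry$provenance == "ratio"]
  # ratios whose numerator is not itself a time total halve exactly
  time_num <- grepl("Sum_[ciw]time\\)/", ratios)
  for (r in ratios[!time_num]) {
    expect_equal(c2[[r]], c1[[r]] / 2)
  }
  for (r in registry$name[registry$provenance == "time_relation"]) {
    expect_equal(c2[[r]], c1[[r]])
  }
})

test_that("pca augmentation appends centred components with ordered variance", {
  set.seed(41)
  base <- base_features(list(fixed_log()))
  many <- dplyr::bind_rows(lapply(1:30, function(i) {
    row <- base
    for (nm in names(row)) row[[nm]] <- row[[nm]] * exp(rnorm(1, 0, 0.2))
    row
  }))
  comp <- composite_features(many)
  aug <- pca_augment(comp)
  registry <- attr(aug$table, "registry")
  expect_equal(nrow(registry), 238)
  expect_equal(sum(registry$provenance == "pca"), 22)
  pcs <- as.matrix(aug$table[, paste0("PCA_VAL_", 1:22)])
  expect_equal(colMeans(pcs), setNames(rep(0, 22), colnames(pcs)),
               tolerance = 1e-10)
  vars <- apply(pcs, 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  expect_false(aug$capped)
})

test_that("pca components cap at the available rank and are flagged", {
  base <- base_features(list(fixed_log()))
  few <- dplyr::bind_rows(lapply(1:5, function(i) {
    row <- base
    row[["Mean(Dice)"]] <- row[["Mean(Dice)"]] + i / 10
    row
  }))
  aug <- pca_augment(composite_features(few))
  expect_true(aug$capped)
  expect_lt(sum(attr(aug$table, "registry")$provenance == "pca"), 22)
})

test_that("feature extraction is a pure function of the logs", {
  co <- cohort_small()
  a <- log_feature_table(co)
  b <- log_feature_table(co)
  expect_identical(a$table, b$table)
  key <- c("sample_id", "subject", "prototype")
  expect_equal(sort(a$table$sample_id), sort(co$manifest$sample_id))
})

test_that("pca scores are sign-invariant under sample permutation", {
  set.seed(42)
  base <- base_features(list(fixed_log()))
  many <- dplyr::bind_rows(lapply(1:12, function(i) {
    row <- base
    for (nm in names(row)) row[[nm]] <- row[[nm]] * exp(rnorm(1, 0, 0.3))
    row
  }))
  comp <- composite_features(many)
  perm <- sample(12)
  aug1 <- pca_augment(comp)
  aug2 <- pca_augment(comp[perm, ])
  p1 <- as.matrix(aug1$table[perm, grep("PCA_VAL", names(aug1$table))])
  p2 <- as.matrix(aug2$table[, grep("PCA_VAL", names(aug2$table))])
  for (j in seq_len(ncol(p1))) {
    expect_true(isTRUE(all.equal(p1[, j], p2[, j])) ||
                  isTRUE(all.equal(p1[, j], -p2[, j])))
  }
})

test_that("the applied pca transform reproduces the fitted scores", {
  set.seed(43)
  base <- base_features(list(fixed_log()))
  many <- dplyr::bind_rows(lapply(1:10, function(i) {
    row <- base
    for (nm in names(row)) row[[nm]] <- row[[nm]] * exp(rnorm(1, 0, 0.3))
    row
  }))
  comp <- composite_features(many)
  aug <- pca_augment(comp)
  re <- apply_pca_transform(comp, aug$transform)
  nms <- aug$transform$names
  expect_equal(as.matrix(re[, nms]), as.matrix(aug$table[, nms]),
               ignore_attr = TRUE)
})

test_that("feature tables round-trip to csv with a registry sidecar", {
  co <- cohort_small()
  ft <- log_feature_table(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  expect_true(file.exists(sub("\\.csv$", ".registry.json", path)))
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), nrow(ft$table))
  expect_true(all(ft$registry$name %in% names(back)))
})
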