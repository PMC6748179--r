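# the fixed per-segmentation scalar catalogue (22 entries); names follow the
# interaction-log feature nomenclature: ctime/itime/wtime = computation,
# interaction and elapsed wall time
per_seg_feature_names <- c(
  "#Interactions", "#Undos", "#Seeds", "#FG_seeds", "#BG_seeds", "#Toggles",
  "Sum_ctime", "Sum_itime", "Sum_wtime", "Med_ctime", "Med_itime",
  "Med_wtime", "Dice", "Jaccard", "Rand_index", "ROC_AUC", "RAVD", "MSE",
  "LOG", "OBJ_TPR", "OBJ_TNR", "Dice_AUC"
)

user_seed_origins <- c("user_scribble", "system_suggested", "long_press")

impute0 <- function(f) {
  v <- tryCatch(f, error = function(e) 0)
  if (!is.finite(v)) 0 else v
}

#' Per-segmentation scalar features of one interaction log
#'
#' The fixed 22-value catalogue extracted from a single session: event
#' counts (interactions, undos, seeds by label, label toggles), the three
#' time totals and their per-event medians (computation, interaction and
#' elapsed wall time), and the quality of the final segmentation against
#' the ground truth (Dice, Jaccard, Rand index, ROC AUC and logistic loss
#' of the strength-derived probability map, RAVD, MSE, object-level
#' TPR/TNR) plus the area under the per-interaction Dice trajectory.
#' Metrics undefined on a degenerate session are imputed as 0.
#'
#' @param log An `interaction_log` (with its image/ground truth attached).
#' @return A one-row tibble with the 22 named features.
#' @export
per_segmentation_features <- function(log) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  reseg <- !is.na(ev$dice_after)
  user_seeds <- dplyr::filter(log$seeds, .data$origin %in% user_seed_origins)
  pred <- as_mask(log$result)
  prob <- probability_map(log$result)
  gt <- log$gt
  traj <- dice_trajectory(log)
  ctimes <- ev$computation_time[ev$computation_time > 0]
  itimes <- ev$interaction_time
  interaction_types <- c("add_scribble", "choose_option", "new_points",
                         "long_press")
  vals <- c(
    sum(ev$event_type %in% interaction_types),
    sum(ev$event_type == "undo"),
    nrow(user_seeds),
    sum(user_seeds$label == "foreground"),
    sum(user_seeds$label == "background"),
    sum(ev$event_type == "toggle_label"),
    sum(ev$computation_time),
    sum(ev$interaction_time),
    ev$t_wall[nrow(ev)] - ev$t_wall[1],
    impute0(median(ctimes)),
    impute0(median(itimes)),
    impute0(median(diff(c(0, ev$t_wall)))),
    impute0(dice(pred, gt)),
    impute0(jaccard(pred, gt)),
    impute0(rand_index(pred, gt)),
    impute0(roc_auc(prob, gt)),
    impute0(ravd(pred, gt)),
    impute0(mse(pred, gt)),
    impute0(log_loss(prob, gt)),
    impute0(obj_tpr(pred, gt)),
    impute0(obj_tnr(pred, gt)),
    attr(traj, "auc")
  )
  tibble::as_tibble(as.list(setNames(vals, per_seg_feature_names)))
}

seed_coord_feature_names <- c(
  "Med(Relative_Seed_Coord_H)", "Med(Relative_Seed_Coord_V)",
  "Std(Relative_Seed_Coord_H)", "Std(Relative_Seed_Coord_V)"
)

#' Base features of one sample (subject-prototype pair)
#'
#' Pools the sample's interaction logs into 48 base features: four seed
#' position statistics (median and standard deviation of the user-placed
#' seeds' relative horizontal and vertical coordinates, pooled over all of
#' the sample's logs) and, for each of the 22 per-segmentation features,
#' its mean and median across the sample's segmentations. A sample without
#' user-placed seeds gets relative position 0.5 and spread 0.
#'
#' @param logs List of `interaction_log` objects of one sample.
#' @return One-row tibble with 48 named features.
#' @export
base_features <- function(logs) {
  stopifnot(length(logs) >= 1)
  per_seg <- dplyr::bind_rows(lapply(logs, per_segmentation_features))
  coords <- dplyr::bind_rows(lapply(logs, function(l) {
    s <- dplyr::filter(l$seeds, .data$origin %in% user_seed_origins)
    tibble::tibble(x = s$x / (ncol(l$image) - 1),
                   y = s$y / (nrow(l$image) - 1))
  }))
  if (nrow(coords) == 0) {
    seed_stats <- c(0.5, 0.5, 0, 0)
  } else {
    seed_stats <- c(median(coords$x), median(coords$y),
                    impute0(sd(coords$x)), impute0(sd(coords$y)))
  }
  agg <- unlist(lapply(per_seg_feature_names, function(f) {
    setNames(c(mean(per_seg[[f]]), median(per_seg[[f]])),
             c(paste0("Mean(", f, ")"), paste0("Med(", f, ")")))
  }))
  tibble::as_tibble(as.list(c(setNames(seed_stats, seed_coord_feature_names),
                              agg)))
}

time_summaries <- c("Mean(Sum_ctime)", "Mean(Sum_itime)", "Mean(Sum_wtime)",
                    "Med(Sum_ctime)", "Med(Sum_itime)", "Med(Sum_wtime)")

#' The composite feature catalogue: 48 base columns to 216
#'
#' Adds 168 composite columns to the 48 base features, since the base
#' features individually correlate only weakly with questionnaire results:
#' (a) each of the 4 seed-position features divided by each of the 6 time
#' summaries (mean/median of total computation, interaction and wall time);
#' (b) each mean-aggregated per-segmentation feature divided by each mean
#' time summary (22 x 3); (c) the same for the median aggregates (22 x 3);
#' and (d) the 12 ordered relations among the time summaries themselves
#' (mean with mean, median with median), prefixed `TimeRel` to keep names
#' unique. Division by zero is imputed as 0. The column registry records
#' the provenance of every column.
#'
#' @param base Tibble whose feature columns are the 48 base features (id
#'   columns are carried through).
#' @return Tibble with 216 feature columns, registry in attribute
#'   `"registry"`.
#' @export
composite_features <- function(base) {
  out <- tibble::as_tibble(base)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  registry <- tibble::tibble(name = character(), provenance = character())
  reg <- function(names, prov) {
    registry <<- dplyr::bind_rows(registry,
                                  tibble::tibble(name = names,
                                                 provenance = prov))
  }
  base_cols <- c(seed_coord_feature_names,
                 as.vector(t(outer(c("Mean(", "Med("), per_seg_feature_names,
                                   function(p, f) paste0(p, f, ")")))))
  reg(base_cols, "base")
  for (sf in seed_coord_feature_names) {
    for (ts in time_summaries) {
      nm <- paste0(sf, "/", ts)
      out[[nm]] <- safe_div(base[[sf]], base[[ts]])
      reg(nm, "ratio")
    }
  }
  for (agg in c("Mean", "Med")) {
    tss <- paste0(agg, "(Sum_", c("ctime", "itime", "wtime"), ")")
    for (f in per_seg_feature_names) {
      num <- paste0(agg, "(", f, ")")
      for (ts in tss) {
        nm <- paste0(num, "/", ts)
        out[[nm]] <- safe_div(base[[num]], base[[ts]])
        reg(nm, "ratio")
      }
    }
  }
  for (agg in c("Mean", "Med")) {
    tss <- paste0(agg, "(Sum_", c("ctime", "itime", "wtime"), ")")
    for (a in tss) {
      for (b in setdiff(tss, a)) {
        nm <- paste0("TimeRel_", a, "/", b)
        out[[nm]] <- safe_div(base[[a]], base[[b]])
        reg(nm, "time_relation")
      }
    }
  }
  attr(out, "registry") <- registry
  out
}

#' Augment a feature table with principal-component scores
#'
#' Standardises the 216 log-derived columns (constant columns are dropped
#' from the fit but retained in the table) and appends the leading
#' `ceiling(0.1 * 216) = 22` principal-component score columns
#' (`PCA_VAL_1` ...), to hand the downstream feature selection a set of
#' maximised-variance summaries. Fewer samples than requested components
#' cap the count (flagged). The fitted transform (centres, scales,
#' rotation) is returned so it can be applied to new samples.
#'
#' @param table Output of [composite_features()].
#' @param n_components Number of component columns to append.
#' @return List with `table` (238 feature columns) and `transform`; the
#'   extended registry travels in `attr(table, "registry")`.
#' @export
pca_augment <- function(table, n_components = ceiling(0.1 * 216)) {
  registry <- attr(table, "registry")
  feat_cols <- registry$name
  x <- as.matrix(table[, feat_cols])
  keep <- apply(x, 2, function(col) var(col) > 0)
  capped <- min(n_components, nrow(x) - 1, sum(keep))
  fit <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE,
                rank. = capped)
  scores <- fit$x
  nms <- paste0("PCA_VAL_", seq_len(ncol(scores)))
  out <- table
  for (i in seq_len(ncol(scores))) out[[nms[i]]] <- scores[, i]
  attr(out, "registry") <- dplyr::bind_rows(
    registry, tibble::tibble(name = nms, provenance = "pca")
  )
  transform <- list(center = fit$center, scale = fit$scale,
                    rotation = fit$rotation, columns = feat_cols[keep],
                    names = nms)
  list(table = out, transform = transform,
       capped = capped < n_components)
}

#' Apply a fitted PCA transform to new samples
#'
#' @param table A 216-column feature table ([composite_features()]).
#' @param transform The transform returned by [pca_augment()].
#' @return The table with the component columns appended.
#' @export
apply_pca_transform <- function(table, transform) {
  x <- scale(as.matrix(table[, transform$columns]),
             center = transform$center, scale = transform$scale)
  scores <- x %*% transform$rotation
  out <- table
  for (i in seq_along(transform$names)) {
    out[[transform$names[i]]] <- scores[, i]
  }
  out
}

#' Feature table of a simulated cohort
#'
#' Runs the full deterministic extraction — 22 per-segmentation scalars,
#' 48 base features per sample, the 216-column composite catalogue and the
#' appended principal-component scores — over every sample of a cohort.
#'
#' @param cohort A `usability_cohort` from [simulate_cohort()], or a tibble
#'   like its `logs` element (columns `sample_id`, `subject`, `prototype`,
#'   `log`).
#' @param pca Whether to append the component columns.
#' @return List with `table` (one row per sample; id columns `sample_id`,
#'   `subject`, `prototype` followed by the feature columns), `registry`
#'   and, when `pca` is `TRUE`, the fitted `transform`.
#' @export
log_feature_table <- function(cohort, pca = TRUE) {
  logs <- if (inherits(cohort, "usability_cohort")) cohort$logs else cohort
  by_sample <- split(seq_len(nrow(logs)), logs$sample_id)
  ids <- dplyr::distinct(logs[, c("sample_id", "subject", "prototype")])
  rows <- lapply(names(by_sample), function(sid) {
    b <- base_features(logs$log[by_sample[[sid]]])
    dplyr::mutate(b, sample_id = sid, .before = 1)
  })
  base <- dplyr::left_join(ids, dplyr::bind_rows(rows), by = "sample_id")
  comp <- composite_features(base)
  if (!pca) {
    return(list(table = comp, registry = attr(comp, "registry")))
  }
  aug <- pca_augment(comp)
  list(table = aug$table, registry = attr(aug$table, "registry"),
       transform = aug$transform, capped = aug$capped)
}

#' Write a feature table with its column registry sidecar
#'
#' The table goes to CSV; the registry (and, if given, the PCA transform
#' parameters) to a JSON sidecar next to it.
#'
#' @param features Result of [log_feature_table()].
#' @param path CSV path; the sidecar replaces the extension with
#'   `.registry.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features$table, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".registry.json", path)
  payload <- list(registry = features$registry)
  if (!is.null(features$transform)) {
    payload$pca <- list(
      center = as.list(features$transform$center),
      scale = as.list(features$transform$scale),
      columns = features$transform$columns,
      names = features$transform$names,
      rotation = features$transform$rotation
    )
  }
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
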