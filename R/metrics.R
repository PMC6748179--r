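check_pair <- function(pred, ref) {
  stopifnot(is.matrix(pred) || is.vector(pred))
  if (!identical(dim(pred), dim(ref)) && length(pred) != length(ref)) {
    stop("predicted and reference masks must share their shape", call. = FALSE)
  }
  list(a = as.logical(pred), b = as.logical(ref))
}

check_nonempty_ref <- function(ref, metric) {
  if (!any(ref)) {
    stop("metric '", metric, "' is undefined for an empty reference mask",
         call. = FALSE)
  }
}

#' Segmentation overlap and error metrics
#'
#' Standard similarity measures between a predicted and a reference binary
#' mask, used both as interaction-log features and as acceptance checks:
#' Sorensen-Dice `2|A.B| / (|A| + |B|)`, Jaccard, the (pair-counting) Rand
#' index, the relative absolute area difference `|A_pred - A_ref| / A_ref`,
#' per-pixel mean squared error, and object-level true positive / negative
#' rates (foreground recall and background recall).
#'
#' @param pred Predicted mask (logical, `TRUE` = foreground).
#' @param ref Reference (ground truth) mask of the same shape.
#' @return A scalar; `dice`, `jaccard`, `rand_index`, `mse`, `obj_tpr`,
#'   `obj_tnr` lie in `[0, 1]`, `ravd` in `[0, Inf)`.
#' @name mask_metrics
NULL

#' @rdname mask_metrics
#' @export
dice <- function(pred, ref) {
  p <- check_pair(pred, ref)
  check_nonempty_ref(p$b, "dice")
  denom <- sum(p$a) + sum(p$b)
  2 * sum(p$a & p$b) / denom
}

#' @rdname mask_metrics
#' @export
jaccard <- function(pred, ref) {
  p <- check_pair(pred, ref)
  check_nonempty_ref(p$b, "jaccard")
  sum(p$a & p$b) / sum(p$a | p$b)
}

#' @rdname mask_metrics
#' @export
rand_index <- function(pred, ref) {
  p <- check_pair(pred, ref)
  n <- length(p$a)
  if (n < 2) stop("rand index needs at least two elements", call. = FALSE)
  nij <- table(p$a, p$b)
  ai <- rowSums(nij)
  bj <- colSums(nij)
  ch2 <- function(m) sum(m * (m - 1) / 2)
  (ch2(n) - ch2(ai) - ch2(bj) + 2 * ch2(nij)) / ch2(n)
}

#' @rdname mask_metrics
#' @export
ravd <- function(pred, ref) {
  p <- check_pair(pred, ref)
  check_nonempty_ref(p$b, "ravd")
  abs(sum(p$a) - sum(p$b)) / sum(p$b)
}

#' @rdname mask_metrics
#' @export
mse <- function(pred, ref) {
  p <- check_pair(pred, ref)
  mean((as.numeric(p$a) - as.numeric(p$b))^2)
}

#' @rdname mask_metrics
#' @export
obj_tpr <- function(pred, ref) {
  p <- check_pair(pred, ref)
  check_nonempty_ref(p$b, "obj_tpr")
  sum(p$a & p$b) / sum(p$b)
}

#' @rdname mask_metrics
#' @export
obj_tnr <- function(pred, ref) {
  p <- check_pair(pred, ref)
  if (all(p$b)) {
    stop("metric 'obj_tnr' is undefined without reference background",
         call. = FALSE)
  }
  sum(!p$a & !p$b) / sum(!p$b)
}

#' Ranking and probabilistic segmentation scores
#'
#' `roc_auc()` computes the area under the receiver operating characteristic
#' curve of a per-pixel score map against a binary reference, via the
#' rank-sum formulation with ties averaged (equivalent to exhaustive
#' counting over all positive/negative pixel pairs). `log_loss()` is the
#' mean cross-entropy of a foreground-probability map, with probabilities
#' clipped to `[delta, 1 - delta]`.
#'
#' @param scores Numeric matrix/vector of per-pixel foreground scores.
#' @param probs Numeric matrix/vector of foreground probabilities.
#' @param ref Reference mask; must contain both classes for `roc_auc`.
#' @param delta Clipping constant for `log_loss`.
#' @return A scalar: AUC in `[0, 1]`; log loss `>= 0`.
#' @name score_metrics
NULL

#' @rdname score_metrics
#' @export
roc_auc <- function(scores, ref) {
  y <- as.logical(ref)
  s <- as.numeric(scores)
  stopifnot(length(s) == length(y), all(is.finite(s)))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc is undefined for a one-class reference", call. = FALSE)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname score_metrics
#' @export
log_loss <- function(probs, ref, delta = 1e-6) {
  y <- as.numeric(as.logical(ref))
  p <- pmin(pmax(as.numeric(probs), delta), 1 - delta)
  stopifnot(length(p) == length(y))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice trajectory of an interaction log
#'
#' Extracts the per-interaction Dice values a session recorded after each
#' re-segmentation, together with an area-under-trajectory summary (the mean
#' Dice over re-segmentation events) describing how quickly the session
#' converged towards the ground truth.
#'
#' @param log An `interaction_log`.
#' @return A tibble with columns `n` (interaction) and `dice`, carrying the
#'   summary as attribute `"auc"`.
#' @export
dice_trajectory <- function(log) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  keep <- !is.na(ev$dice_after)
  out <- tibble::tibble(n = seq_len(sum(keep)), dice = ev$dice_after[keep])
  attr(out, "auc") <- if (nrow(out)) mean(out$dice) else 0
  structure(out, class = c("dice_trajectory", class(out)))
}
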