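#' Canonical AttrakDiff-2 word pairs
#'
#' The 28 complementary adjective pairs, clustered into the four quality
#' groups: pragmatic quality (PQ), attractiveness (ATT), hedonic identity
#' (HQ-I) and hedonic stimulus (HQ-S), seven pairs each, in canonical order.
#' Shipped as a plain-text data file.
#'
#' @return Tibble with columns `group`, `item`, `negative`, `positive`.
#' @export
attrakdiff_items <- function() {
  path <- system.file("extdata", "attrakdiff_items.csv", package = "iseval")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

attrak_groups <- c("PQ", "ATT", "HQ-I", "HQ-S")

validate_sus <- function(responses) {
  req <- c("subject", "item", "value")
  if (!is.data.frame(responses) || !all(req %in% names(responses))) {
    stop("SUS responses must have columns subject, item, value", call. = FALSE)
  }
  if (!all(responses$value %in% 0:4)) {
    stop("SUS item values must be integers in 0..4", call. = FALSE)
  }
  counts <- table(responses$subject)
  if (any(counts != 10) ||
      !all(tapply(responses$item, responses$subject,
                  function(i) setequal(i, 1:10)))) {
    stop("each subject needs exactly one response to items 1..10",
         call. = FALSE)
  }
  tibble::as_tibble(responses)
}

#' Score the System Usability Scale
#'
#' The composite SUS score over all respondents:
#' `(2.5 / S) * sum_s [ sum_{odd i} x_si + sum_{even i} (4 - x_si) ]`,
#' where items are coded 0..4 and even-indexed statements are negatively
#' worded, hence reversed. An all-neutral respondent (all items 2) scores
#' 50; the most favourable response (4 on odd, 0 on even items) scores 100.
#'
#' @param responses Data frame with columns `subject`, `item` (1..10) and
#'   `value` (0..4), or a bare numeric vector of 10 item values for a single
#'   respondent.
#' @return The SUS score in `[0, 100]`.
#' @export
#' @examples
#' sus_score(rep(2, 10))  # 50
sus_score <- function(responses) {
  if (is.numeric(responses) && is.null(dim(responses))) {
    responses <- tibble::tibble(subject = "s1", item = seq_along(responses),
                                value = responses)
  }
  responses <- validate_sus(responses)
  per_subject <- tapply(
    ifelse(responses$item %% 2 == 1, responses$value, 4 - responses$value),
    responses$subject, sum
  )
  2.5 * mean(per_subject)
}

# published adjective-anchor means on the SUS scale
sus_default_anchors <- c(
  "worst imaginable" = 12.5, "awful" = 20.3, "poor" = 35.7, "OK" = 50.9,
  "good" = 71.4, "excellent" = 85.5, "best imaginable" = 90.9
)

#' Map a SUS score to an adjective rating
#'
#' Classifies a score on the seven-adjective scale (worst imaginable ...
#' best imaginable) by the nearest anchor mean. The default anchors are the
#' published per-adjective mean SUS scores; they are configurable since the
#' original study reported a full score distribution per adjective.
#'
#' @param score SUS score(s) in `[0, 100]`.
#' @param anchors Named numeric vector of per-adjective anchor means.
#' @return Character vector of adjectives.
#' @export
#' @examples
#' sus_adjective(c(88, 67, 82))
sus_adjective <- function(score, anchors = sus_default_anchors) {
  stopifnot(all(score >= 0), all(score <= 100))
  names(anchors)[vapply(score, function(s) which.min(abs(anchors - s)),
                        integer(1))]
}

validate_attrakdiff <- function(responses) {
  req <- c("subject", "group", "item", "value")
  if (!is.data.frame(responses) || !all(req %in% names(responses))) {
    stop("AttrakDiff-2 responses must have columns subject, group, item, value",
         call. = FALSE)
  }
  if (!all(responses$value %in% 1:7)) {
    stop("AttrakDiff-2 item values must be integers in 1..7", call. = FALSE)
  }
  if (!all(responses$group %in% attrak_groups)) {
    stop("groups must be PQ, ATT, HQ-I, HQ-S", call. = FALSE)
  }
  ok <- tapply(responses$item, list(responses$subject, responses$group),
               function(i) setequal(i, 1:7))
  if (anyNA(ok) || !all(ok)) {
    stop("each subject needs one response to items 1..7 in every group",
         call. = FALSE)
  }
  tibble::as_tibble(responses)
}

#' Score the AttrakDiff-2 questionnaire
#'
#' Per quality group `g`, the score is the mean response over all subjects
#' and the group's seven items, `(1 / (7 S)) * sum_s sum_i x_si^g`, on the
#' 1..7 scale. The overall hedonic quality HQ is the mean of HQ-I and HQ-S.
#'
#' @param responses Data frame with columns `subject`, `group` (PQ, ATT,
#'   HQ-I, HQ-S), `item` (1..7) and `value` (1..7), in canonical item order
#'   (de-randomise first if needed).
#' @return One-row tibble with columns `PQ`, `ATT`, `HQ-I`, `HQ-S`, `HQ`.
#' @export
attrakdiff_scores <- function(responses) {
  responses <- validate_attrakdiff(responses)
  g <- tapply(responses$value, responses$group, mean)
  out <- tibble::tibble(
    PQ = g[["PQ"]], ATT = g[["ATT"]],
    `HQ-I` = g[["HQ-I"]], `HQ-S` = g[["HQ-S"]]
  )
  out$HQ <- (out$`HQ-I` + out$`HQ-S`) / 2
  out
}

#' Randomise and de-randomise AttrakDiff-2 presentation
#'
#' Before administration, both the order of the 28 word pairs and the order
#' of the two poles within each pair are randomised. `randomize_presentation()`
#' draws such a scheme; `de_randomize()` restores a response vector recorded
#' under a scheme to canonical order, reversing flipped pairs by
#' `x -> 8 - x`. The round trip is the identity.
#'
#' @param seed Integer seed for the scheme.
#' @param responses Data frame with columns `position` (1..28, presentation
#'   order) and `value` plus any identifier columns.
#' @param scheme A scheme produced by `randomize_presentation()`.
#' @return `randomize_presentation()`: tibble with `position`, `group`,
#'   `item`, `flipped`; `de_randomize()`: the responses in canonical order
#'   with columns `group`, `item`, `value`.
#' @name presentation
NULL

#' @rdname presentation
#' @export
randomize_presentation <- function(seed) {
  items <- attrakdiff_items()
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(28)
    tibble::tibble(
      position = 1:28,
      group = items$group[perm],
      item = items$item[perm],
      flipped = sample(c(TRUE, FALSE), 28, replace = TRUE)
    )
  })
}

#' @rdname presentation
#' @export
de_randomize <- function(responses, scheme) {
  stopifnot(all(c("position", "value") %in% names(responses)),
            nrow(scheme) == 28)
  merged <- dplyr::inner_join(tibble::as_tibble(responses), scheme,
                              by = "position")
  merged$value <- ifelse(merged$flipped, 8 - merged$value, merged$value)
  extra <- setdiff(names(responses), c("position", "value"))
  dplyr::arrange(
    merged[, c(extra, "group", "item", "value")],
    factor(.data$group, levels = attrak_groups), .data$item
  )
}

# conventional 3 x 3 partition of the PQ x HQ plane (cut points 3 and 5);
# rows: HQ band (low, mid, high), columns: PQ band
portfolio_default_fields <- matrix(
  c("superfluous", "superfluous", "too task-oriented",
    "superfluous", "neutral", "task-oriented",
    "too self-oriented", "self-oriented", "desired"),
  nrow = 3, byrow = TRUE,
  dimnames = list(hq = c("low", "mid", "high"), pq = c("low", "mid", "high"))
)

band <- function(x, cuts = c(3, 5)) {
  ifelse(x < cuts[1], 1L, ifelse(x <= cuts[2], 2L, 3L))
}

#' AttrakDiff-2 portfolio representation
#'
#' Summarises per-subject PQ and HQ scores of one system as a point (the
#' means) with a confidence rectangle (two-sided t-based confidence interval
#' in each dimension). If the rectangle lies entirely inside one of the
#' named fields of the conventional 3 x 3 partition of the PQ-HQ plane, that
#' field's adjective describes the system; otherwise all overlapped fields
#' are reported. With a single subject the rectangle is undefined and
#' flagged.
#'
#' @param scores Data frame with one row per subject and columns `PQ` and
#'   `HQ` (e.g. stacked one-subject results of [attrakdiff_scores()]).
#' @param confidence Confidence level of the rectangle.
#' @param fields 3 x 3 character matrix naming the fields (rows: HQ bands
#'   low/mid/high, columns: PQ bands), `cuts` the two cut points.
#' @param cuts Numeric cut points of the partition on both axes.
#' @return An `attrakdiff_portfolio` object (tibble with one row: means,
#'   CI half-widths, subject count, field labels).
#' @export
portfolio <- function(scores, confidence = 0.95,
                      fields = portfolio_default_fields, cuts = c(3, 5)) {
  stopifnot(all(c("PQ", "HQ") %in% names(scores)))
  n <- nrow(scores)
  half <- function(x) {
    if (n < 2) return(NA_real_)
    qt(1 - (1 - confidence) / 2, n - 1) * sd(x) / sqrt(n)
  }
  pq <- mean(scores$PQ)
  hq <- mean(scores$HQ)
  hw_pq <- half(scores$PQ)
  hw_hq <- half(scores$HQ)
  label <- if (n < 2) {
    fields[band(hq, cuts), band(pq, cuts)]
  } else {
    pq_bands <- unique(band(c(pq - hw_pq, pq, pq + hw_pq), cuts))
    hq_bands <- unique(band(c(hq - hw_hq, hq, hq + hw_hq), cuts))
    unique(as.character(fields[hq_bands, pq_bands]))
  }
  structure(
    tibble::tibble(
      pq_mean = pq, hq_mean = hq, pq_half_width = hw_pq,
      hq_half_width = hw_hq, n = n, confidence = confidence,
      fields = list(label), single_subject = n < 2
    ),
    class = c("attrakdiff_portfolio", "tbl_df", "tbl", "data.frame"),
    cuts = cuts, field_names = fields
  )
}

#' Compare two portfolio rectangles for significance
#'
#' Two systems differ significantly in a dimension only if their confidence
#' rectangles do not overlap in that dimension's one-dimensional projection.
#'
#' @param a,b `attrakdiff_portfolio` objects.
#' @return Tibble with `dimension`, `overlap`, `significant`.
#' @export
portfolio_significance <- function(a, b) {
  one <- function(ma, ha, mb, hb, dim) {
    lo_a <- ma - ha
    hi_a <- ma + ha
    lo_b <- mb - hb
    hi_b <- mb + hb
    ov <- lo_a <= hi_b && lo_b <= hi_a
    tibble::tibble(dimension = dim, overlap = ov, significant = !ov)
  }
  dplyr::bind_rows(
    one(a$pq_mean, a$pq_half_width, b$pq_mean, b$pq_half_width, "PQ"),
    one(a$hq_mean, a$hq_half_width, b$hq_mean, b$hq_half_width, "HQ")
  )
}

#' Read and write questionnaire responses as CSV
#'
#' One row per subject-item with the group (`"SUS"` for SUS rows), item
#' index, value and optional presentation metadata columns.
#'
#' @param responses Response data frame.
#' @param path File path.
#' @return `read_questionnaire()` a tibble; the writer returns `path`
#'   invisibly.
#' @name questionnaire_io
NULL

#' @rdname questionnaire_io
#' @export
write_questionnaire <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname questionnaire_io
#' @export
read_questionnaire <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             check.names = FALSE))
}
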