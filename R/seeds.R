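#' Construct a set of seed points
#'
#' Seeds are the atomic unit of interactive input: a pixel position plus a
#' class label. They are kept in an ordered tibble so the cumulative scribble
#' sets `S^0 subset S^1 subset ...` of a session can be reconstructed from
#' the `n` column (interaction index; 0 is the predefined initialisation).
#'
#' @param x,y Integer pixel coordinates, 0-based, `(x, y)` = (column, row).
#' @param label `"background"` or `"foreground"` (recycled).
#' @param origin Where the seed came from: `"user_scribble"`,
#'   `"system_suggested"`, `"long_press"` or `"border_init"`.
#' @param n Interaction index (recycled).
#' @return A tibble with columns `x`, `y`, `label`, `origin`, `n`.
#' @export
seed_points <- function(x, y, label, origin = "user_scribble", n = 1L) {
  tibble::tibble(
    x = as.integer(x), y = as.integer(y),
    label = rep_len(label, length(x)),
    origin = rep_len(origin, length(x)),
    n = rep_len(as.integer(n), length(x))
  )
}

empty_seeds <- function() seed_points(integer(), integer(), character())

validate_seeds <- function(seeds, image = NULL) {
  req <- c("x", "y", "label")
  if (!is.data.frame(seeds) || !all(req %in% names(seeds))) {
    stop("seeds must be a data frame with columns x, y, label", call. = FALSE)
  }
  seeds <- tibble::as_tibble(seeds)
  if (!all(seeds$label %in% label_levels)) {
    stop("seed labels must be 'background' or 'foreground'", call. = FALSE)
  }
  if (!is.null(image) && nrow(seeds) > 0) {
    if (any(seeds$x < 0) || any(seeds$y < 0) ||
        any(seeds$x >= ncol(image)) || any(seeds$y >= nrow(image))) {
      stop("seed positions must lie inside the image", call. = FALSE)
    }
  }
  if (is.null(seeds$origin)) seeds$origin <- "user_scribble"
  if (is.null(seeds$n)) seeds$n <- 1L
  seeds
}

#' Predefined background seeds along the image border
#'
#' Every session starts from background labels on the image edges, since the
#' object to segment is assumed to lie entirely inside the displayed region.
#' The four corners are always included; additional border pixels are placed
#' every `spacing` pixels along each edge.
#'
#' @param image Numeric image matrix (only its dimensions are used).
#' @param spacing Distance in pixels between consecutive border seeds.
#' @return Seed tibble (`origin = "border_init"`, `n = 0`), all background,
#'   all on row 0, row `h - 1`, column 0 or column `w - 1`.
#' @export
border_background_seeds <- function(image, spacing = 1L) {
  stopifnot(spacing >= 1)
  w <- ncol(image)
  h <- nrow(image)
  along <- function(last) unique(c(seq(0L, last, by = spacing), last))
  top <- cbind(along(w - 1L), 0L)
  bottom <- cbind(along(w - 1L), h - 1L)
  left <- cbind(0L, along(h - 1L))
  right <- cbind(w - 1L, along(h - 1L))
  pos <- unique(rbind(top, bottom, left, right))
  seed_points(pos[, 1], pos[, 2], "background", origin = "border_init", n = 0L)
}

# row-major (y * w + x) ordering index for an h x w matrix, as a vector
# aligned with R's column-major storage
row_major_rank <- function(h, w) {
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  ys * w + xs
}

#' Locations with the most label changes
#'
#' Ranks pixels by the change counter `h` of the previous GrowCut run and
#' returns the top `k` positions — the automaton's most label-uncertain
#' spots, used by the guided prototype with `k = 2`. Ties are broken by
#' row-major scan order. When `h` is identically zero (the previous run never
#' flipped a label) the ranking is uninformative; if `mask` is supplied, the
#' fall-back ranks contour-adjacent pixels first and the result is flagged.
#'
#' @param changes Integer matrix of per-pixel label-change counts.
#' @param k Number of positions to return.
#' @param mask Optional current foreground mask for the all-zero fall-back.
#' @return Tibble `x`, `y`, `value` in descending value order, with attribute
#'   `"fallback"` (`TRUE` when the all-zero fall-back fired).
#' @export
max_change_locations <- function(changes, k = 2L, mask = NULL) {
  stopifnot(k >= 1)
  h <- nrow(changes)
  w <- ncol(changes)
  fallback <- FALSE
  score <- as.numeric(changes)
  if (all(score == 0) && !is.null(mask)) {
    fallback <- TRUE
    contour <- contour_pixels(mask)
    if (any(contour)) {
      d <- as.matrix(EBImage::distmap(ifelse(contour, 0, 1)))
      score <- as.numeric(1 / (1 + d))
    }
  }
  ord <- order(-score, row_major_rank(h, w))
  top <- ord[seq_len(min(k, length(ord)))]
  out <- tibble::tibble(
    x = (top - 1L) %/% h,
    y = (top - 1L) %% h,
    value = as.numeric(changes)[top]
  )
  attr(out, "fallback") <- fallback
  out
}

# foreground pixels with at least one non-foreground Moore neighbour
contour_pixels <- function(mask) {
  if (is.null(mask)) return(matrix(FALSE, 1, 1))
  if (!any(mask)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  all_nb <- matrix(TRUE, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      all_nb <- all_nb & pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
  }
  mask & !all_nb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

min_max_norm <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] == 0) {
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

gradient_magnitude <- function(image) {
  h <- nrow(image)
  w <- ncol(image)
  # central differences with replicated borders
  left <- image[, c(1, seq_len(w - 1))]
  right <- image[, c(seq_len(w - 1) + 1, w)]
  up <- image[c(1, seq_len(h - 1)), ]
  down <- image[c(seq_len(h - 1) + 1, h), ]
  sqrt(((right - left) / 2)^2 + ((down - up) / 2)^2)
}

#' Influence map for new seed point locations
#'
#' Scores every pixel as a candidate for the next suggested seed by a
#' weighted sum of three approximated influence maps: the gradient magnitude
#' of the image, the label-change counts of the previous segmentation
#' weighted by the empirically determined factor 17/12, and the proximity of
#' each pixel to the current contour line. Each component is min-max
#' normalised to `[0, 1]` before the sum, since the three raw maps live on
#' incommensurable scales; an all-zero component normalises to zero. The
#' contour component is `1 / (1 + d)` with `d` the Euclidean distance to the
#' nearest contour pixel (proximity must score high so candidates sample the
#' current boundary), and is zero when the mask has no contour.
#'
#' Because of the min-max normalisation, the map is invariant under affine
#' rescaling of the image intensities.
#'
#' @param image Numeric image matrix.
#' @param changes Label-change count matrix from the previous run.
#' @param mask Current foreground mask (logical), or `NULL` before the first
#'   segmentation.
#' @param change_weight Weight of the change-counter component.
#' @return An `influence_map` object: the combined map (matrix) with the
#'   three normalised components retained as attribute `"components"`.
#' @export
influence_map <- function(image, changes, mask = NULL,
                          change_weight = 17 / 12) {
  stopifnot(identical(dim(image), dim(changes)))
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(image)))
  grad <- min_max_norm(gradient_magnitude(image))
  chg <- min_max_norm(changes * 1.0)
  contour <- if (is.null(mask)) matrix(FALSE, nrow(image), ncol(image)) else contour_pixels(mask)
  if (any(contour)) {
    d <- as.matrix(EBImage::distmap(ifelse(contour, 0, 1)))
    prox <- min_max_norm(1 / (1 + d))
  } else {
    prox <- matrix(0, nrow(image), ncol(image))
  }
  m <- grad + change_weight * chg + prox
  structure(m, class = c("influence_map", "matrix", "array"),
            components = list(gradient = grad, change = chg, contour = prox))
}

#' Suggest seed points from an influence map
#'
#' Greedy maximum selection: candidates are visited in descending map value
#' (row-major order on ties) and accepted unless within `min_separation`
#' (Chebyshev distance) of an already accepted position — extracting many
#' points from a raw argmax would otherwise produce impractical local
#' clusters. Each accepted seed is labelled automatically: foreground if it
#' lies inside the current segmentation mask, background otherwise.
#'
#' @param map Influence map matrix ([influence_map()]).
#' @param mask Current foreground mask used for automatic labelling.
#' @param j Number of seeds requested (around 20 in the joint prototype).
#' @param min_separation Minimum Chebyshev distance between suggestions;
#'   default `max(3, ceiling(0.03 * min(w, h)))`.
#' @param n Interaction index stamped on the seeds.
#' @return Seed tibble (`origin = "system_suggested"`), at most `j` rows; if
#'   fewer admissible positions exist the attribute `"shortfall"` is `TRUE`.
#' @export
suggest_seeds <- function(map, mask, j = 20L, min_separation = NULL, n = 1L) {
  stopifnot(j >= 1)
  h <- nrow(map)
  w <- ncol(map)
  if (is.null(min_separation)) {
    min_separation <- max(3, ceiling(0.03 * min(w, h)))
  }
  ord <- order(-as.numeric(map), row_major_rank(h, w))
  sel_x <- integer(0)
  sel_y <- integer(0)
  for (i in ord) {
    if (length(sel_x) >= j) break
    x <- (i - 1L) %/% h
    y <- (i - 1L) %% h
    if (length(sel_x) > 0 &&
        any(pmax(abs(sel_x - x), abs(sel_y - y)) < min_separation)) {
      next
    }
    sel_x <- c(sel_x, x)
    sel_y <- c(sel_y, y)
  }
  labels <- ifelse(mask[cbind(sel_y + 1L, sel_x + 1L)],
                   "foreground", "background")
  out <- seed_points(sel_x, sel_y, labels, origin = "system_suggested", n = n)
  out$value <- map[cbind(sel_y + 1L, sel_x + 1L)]
  attr(out, "shortfall") <- length(sel_x) < j
  out
}

#' Seed from a long-press interaction
#'
#' A long-press expresses the wish to change the current labelling at a
#' location, so the new seed's label is the inverse of the current mask label
#' there.
#'
#' @param mask Current foreground mask.
#' @param x,y Pixel position (0-based).
#' @param n Interaction index.
#' @return A one-row seed tibble with `origin = "long_press"`.
#' @export
long_press_seed <- function(mask, x, y, n = 1L) {
  stopifnot(x >= 0, y >= 0, x < ncol(mask), y < nrow(mask))
  label <- if (mask[y + 1L, x + 1L]) "background" else "foreground"
  seed_points(x, y, label, origin = "long_press", n = n)
}
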