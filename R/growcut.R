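#' GrowCut transition weight
#'
#' Attenuation `g(c_e, c_f) = 1 - ||c_e - c_f|| / max_pairwise`, clamped to
#' `[0, 1]`. `max_pairwise` is the largest pairwise feature distance in the
#' image; a uniform image has `max_pairwise = 0`, in which case the weight is
#' defined as 1 so labels propagate freely.
#'
#' @param c_e,c_f Scalar intensities (vectorised).
#' @param max_pairwise Largest pairwise intensity distance, `>= 0`.
#' @return Weights in `[0, 1]`.
#' @export
transition_weight <- function(c_e, c_f, max_pairwise) {
  stopifnot(max_pairwise >= 0)
  if (max_pairwise == 0) {
    return(rep(1, length(c_e)))
  }
  pmin(pmax(1 - abs(c_e - c_f) / max_pairwise, 0), 1)
}

growcut_state_from_seeds <- function(image, seeds) {
  validate_gray_image(image)
  seeds <- validate_seeds(seeds, image)
  if (nrow(seeds) == 0) {
    stop("at least one seed is required", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  label <- matrix(LBL_NONE, h, w)
  strength <- matrix(0, h, w)
  # later seeds override earlier ones at the same position
  idx <- cbind(seeds$y + 1L, seeds$x + 1L)
  label[idx] <- label_to_code(seeds$label)
  strength[idx] <- 1
  list(
    image = image, label = label, strength = strength,
    changes = matrix(0L, h, w),
    max_pairwise = max(image) - min(image)
  )
}

#' One synchronous GrowCut iteration
#'
#' Advances the automaton by a single generation: every node reads state `t`
#' and writes state `t + 1`. Among the Moore neighbours whose attack strength
#' `theta_f * g(c_e, c_f)` strictly exceeds the defender's strength, the
#' strongest conquers (ties broken by the fixed scan order N, NE, E, SE, S,
#' SW, W, NW). The per-node change counter increments only when the label
#' actually flips.
#'
#' @param state A state list as produced by [growcut()] (with
#'   `keep_state = TRUE`) or built internally from an image plus seeds.
#' @return The updated state, with a logical attribute `"converged"` set when
#'   the iteration was a fixed point.
#' @export
growcut_step <- function(state) {
  res <- growcut_iterate_cpp(state$image, state$label, state$strength,
                             state$changes, state$max_pairwise, 1L)
  out <- state
  out$label <- res$label
  out$strength <- res$strength
  out$changes <- res$changes
  attr(out, "converged") <- res$converged
  out
}

#' Seeded GrowCut segmentation with a label-change counter
#'
#' Runs the cellular automaton to convergence (no label or strength change in
#' a full generation) or for at most `max_iters` generations. Seeds start
#' with strength 1 and can never be conquered, so their labels are invariant.
#' Next to the final label image, the result carries the per-pixel count of
#' label changes accumulated over the run — regions with many changes mark
#' locations where the automaton was uncertain, which downstream seed
#' suggestion exploits.
#'
#' @param image Numeric `h x w` matrix of intensities in `[0, 1]`.
#' @param seeds Seed tibble, see [seed_points()].
#' @param max_iters Iteration cap; defaults to `w * h`, which is always
#'   sufficient for convergence since node strengths increase strictly on
#'   conquest and are bounded by 1.
#' @return An object of class `growcut_result`: list with `label` (integer
#'   matrix: 0 none, 1 background, 2 foreground), `strength`, `changes`
#'   (label-change counts), `iterations`, `converged`, and the `seeds` used.
#' @export
growcut <- function(image, seeds, max_iters = NULL) {
  state <- growcut_state_from_seeds(image, seeds)
  if (is.null(max_iters)) max_iters <- nrow(image) * ncol(image)
  stopifnot(max_iters >= 1)
  res <- growcut_iterate_cpp(state$image, state$label, state$strength,
                             state$changes, state$max_pairwise,
                             as.integer(max_iters))
  structure(
    list(label = res$label, strength = res$strength, changes = res$changes,
         iterations = res$iterations, converged = res$converged,
         seeds = seeds),
    class = "growcut_result"
  )
}

#' @export
print.growcut_result <- function(x, ...) {
  cat(sprintf(
    "<growcut_result> %d x %d, %d seeds, %d iterations (%s), %d fg px\n",
    ncol(x$label), nrow(x$label), nrow(x$seeds), x$iterations,
    if (x$converged) "converged" else "iteration cap hit",
    sum(x$label == LBL_FG)
  ))
  invisible(x)
}

#' Foreground mask of a segmentation result
#'
#' @param result A `growcut_result`.
#' @return Logical matrix, `TRUE` where the final label is foreground.
#' @export
as_mask <- function(result) {
  result$label == LBL_FG
}

#' Soft foreground probability from automaton state
#'
#' GrowCut has no native probabilistic output; the cell strength is the only
#' available confidence. The map is `theta` for foreground-labelled cells,
#' `1 - theta` for background-labelled cells, and 0.5 for unlabelled cells.
#'
#' @param result A `growcut_result`.
#' @return Numeric matrix of foreground probabilities in `[0, 1]`.
#' @export
probability_map <- function(result) {
  p <- matrix(0.5, nrow(result$label), ncol(result$label))
  fg <- result$label == LBL_FG
  bg <- result$label == LBL_BG
  p[fg] <- result$strength[fg]
  p[bg] <- 1 - result$strength[bg]
  p
}
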