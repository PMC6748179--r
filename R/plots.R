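#' Plot an AttrakDiff-2 portfolio
#'
#' Draws the conventional PQ-HQ plane with its named fields and one
#' confidence rectangle per system.
#'
#' @param object An `attrakdiff_portfolio`, or a named list of them (one
#'   per system).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.attrakdiff_portfolio <- function(object, ...) {
  plot_portfolios(list(system = object))
}

#' @rdname autoplot.attrakdiff_portfolio
#' @param portfolios Named list of `attrakdiff_portfolio` objects.
#' @export
plot_portfolios <- function(portfolios) {
  first <- portfolios[[1]]
  cuts <- attr(first, "cuts")
  fields <- attr(first, "field_names")
  edges <- c(1, cuts, 7)
  grid <- tidyr::expand_grid(hq = 1:3, pq = 1:3)
  grid$label <- fields[cbind(grid$hq, grid$pq)]
  grid$xmin <- edges[grid$pq]
  grid$xmax <- edges[grid$pq + 1]
  grid$ymin <- edges[grid$hq]
  grid$ymax <- edges[grid$hq + 1]
  pts <- dplyr::bind_rows(lapply(names(portfolios), function(nm) {
    p <- portfolios[[nm]]
    tibble::tibble(system = nm, pq = p$pq_mean, hq = p$hq_mean,
                   pq_hw = p$pq_half_width, hq_hw = p$hq_half_width)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = grid,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = NA, colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = grid,
      ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                   y = (.data$ymin + .data$ymax) / 2, label = .data$label),
      colour = "grey60", size = 2.8
    ) +
    ggplot2::geom_rect(
      data = pts,
      ggplot2::aes(xmin = .data$pq - .data$pq_hw,
                   xmax = .data$pq + .data$pq_hw,
                   ymin = .data$hq - .data$hq_hw,
                   ymax = .data$hq + .data$hq_hw, fill = .data$system),
      alpha = 0.35
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$pq, y = .data$hq, colour = .data$system)
    ) +
    ggplot2::coord_cartesian(xlim = c(1, 7), ylim = c(1, 7)) +
    ggplot2::labs(x = "Pragmatic quality (PQ)", y = "Hedonic quality (HQ)") +
    ggplot2::theme_minimal()
}

#' Plot per-interaction Dice trajectories
#'
#' Shows how the similarity to the ground truth evolves over the
#' interactions of one or more sessions.
#'
#' @param logs An `interaction_log` or a list of them.
#' @return A ggplot object.
#' @export
plot_dice_trajectories <- function(logs) {
  if (inherits(logs, "interaction_log")) logs <- list(logs)
  df <- dplyr::bind_rows(lapply(seq_along(logs), function(i) {
    tr <- dice_trajectory(logs[[i]])
    tibble::tibble(session = paste0(logs[[i]]$subject, "/",
                                    logs[[i]]$image_id, " #", i),
                   n = c(0, tr$n),
                   dice = c(logs[[i]]$dice_initial, tr$dice),
                   prototype = logs[[i]]$prototype)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$dice,
                                   group = .data$session,
                                   colour = .data$prototype)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Interaction", y = "Dice") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
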