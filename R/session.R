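#' Rule-based robot user policy
#'
#' Parameters of the simulated operator that drives the headless prototype
#' engines. The robot targets segmentation errors against a known ground
#' truth; its sloppiness (placement jitter, mislabelling), pace (lognormal
#' per-event interaction times) and patience (interaction budget, stopping
#' Dice) are the dials through which a latent usability level expresses
#' itself in the interaction logs.
#'
#' @param scribble_length Seeds per scribble stroke (pixels).
#' @param jitter_sd Gaussian positional jitter of seed placement (pixels).
#' @param mislabel_prob Probability of a wrong label per interaction.
#' @param time_meanlog,time_sdlog Lognormal parameters of per-event
#'   interaction time (seconds).
#' @param undo_prob Probability of undoing the previous interaction.
#' @param long_press_prob Probability of a long-press addition per round of
#'   the joint prototype.
#' @param j Number of suggested seeds per round of the joint prototype.
#' @param budget Maximum number of interactions before the session ends.
#' @param stop_dice Dice threshold at which the robot presses finish.
#' @param min_error_px Smallest connected error component the robot still
#'   chases (smaller residual errors also stop the session).
#' @param comp_time_per_iter Simulated computation time per automaton
#'   iteration (seconds).
#' @param pause Fixed idle gap between events (seconds).
#' @param border_spacing Spacing of the predefined border background seeds.
#' @param seed Integer RNG seed of the session.
#' @return A `robot_policy` list.
#' @export
robot_policy <- function(scribble_length = 6L, jitter_sd = 0.5,
                         mislabel_prob = 0.02, time_meanlog = log(2.5),
                         time_sdlog = 0.35, undo_prob = 0.03,
                         long_press_prob = 0.15, j = 20L, budget = 20L,
                         stop_dice = 0.99, min_error_px = 4L,
                         comp_time_per_iter = 0.004, pause = 0.2,
                         border_spacing = 2L, seed = 1L) {
  stopifnot(budget >= 1, mislabel_prob >= 0, mislabel_prob <= 1,
            undo_prob >= 0, undo_prob <= 1, long_press_prob >= 0,
            long_press_prob <= 1, scribble_length >= 1)
  structure(as.list(environment()), class = "robot_policy")
}

# ---- internal session state ------------------------------------------------

session_start <- function(image, gt, prototype, policy, init_seeds,
                          subject = "s1", image_id = "img") {
  sess <- new.env(parent = emptyenv())
  sess$image <- image
  sess$gt <- gt
  sess$prototype <- prototype
  sess$policy <- policy
  sess$subject <- subject
  sess$image_id <- image_id
  sess$seeds <- init_seeds
  sess$batches <- list()       # seed batches of undoable interactions
  sess$prev_results <- list()  # matching segmentation results before each
  sess$events <- list()
  sess$t_wall <- 0
  sess$n <- 0L
  sess$result <- growcut(image, init_seeds)
  sess$dice_initial <- dice(as_mask(sess$result), gt)
  sess
}

session_push_event <- function(sess, type, itime, ctime, dice_after, payload) {
  sess$t_wall <- sess$t_wall + itime + ctime + sess$policy$pause
  sess$events[[length(sess$events) + 1L]] <- list(
    n = sess$n, event_type = type, t_wall = sess$t_wall,
    interaction_time = itime, computation_time = ctime,
    dice_after = dice_after, payload = payload
  )
  invisible(sess)
}

session_commit <- function(sess, batch, type, itime, extra_ctime = 0,
                           result = NULL) {
  sess$n <- sess$n + 1L
  batch$n <- sess$n
  prev <- sess$result
  sess$batches[[length(sess$batches) + 1L]] <- batch
  sess$prev_results[[length(sess$prev_results) + 1L]] <- prev
  sess$seeds <- dplyr::bind_rows(sess$seeds, batch)
  # `result` may carry the already-computed segmentation of the updated seed
  # set (the engines exploit determinism to avoid recomputing it)
  sess$result <- result %||% growcut(sess$image, sess$seeds)
  ctime <- sess$policy$comp_time_per_iter * sess$result$iterations + extra_ctime
  d <- dice(as_mask(sess$result), sess$gt)
  session_push_event(sess, type, itime, ctime, d, list(seeds = batch))
  invisible(sess)
}

#' Undo the latest interaction of a running session
#'
#' Removes the seeds added by the most recent interaction and restores the
#' segmentation that preceded it; the undo itself is logged. Undoing with no
#' reversible interaction left is a no-op that still grows the log by one
#' event.
#'
#' @param sess A session environment as used internally by the prototype
#'   engines.
#' @param itime Interaction time to log for the undo event.
#' @return The session, invisibly.
#' @keywords internal
session_undo <- function(sess, itime = 0.5) {
  if (length(sess$batches) == 0) {
    session_push_event(sess, "undo", itime, 0,
                       dice(as_mask(sess$result), sess$gt), NULL)
    return(invisible(sess))
  }
  k <- length(sess$batches)
  batch <- sess$batches[[k]]
  sess$batches[[k]] <- NULL
  sess$seeds <- dplyr::anti_join(
    sess$seeds, batch, by = c("x", "y", "label", "origin", "n")
  )
  sess$result <- sess$prev_results[[k]]
  sess$prev_results[[k]] <- NULL
  session_push_event(sess, "undo", itime, 0,
                     dice(as_mask(sess$result), sess$gt), NULL)
  invisible(sess)
}

session_finish <- function(sess, itime) {
  session_push_event(sess, "finish", itime, 0, NA_real_, NULL)
  events <- dplyr::bind_rows(lapply(sess$events, function(e) {
    tibble::tibble(
      n = e$n, event_type = e$event_type, t_wall = e$t_wall,
      interaction_time = e$interaction_time,
      computation_time = e$computation_time,
      dice_after = e$dice_after, payload = list(e$payload)
    )
  }))
  structure(
    list(subject = sess$subject, prototype = sess$prototype,
         image_id = sess$image_id, events = events, seeds = sess$seeds,
         result = sess$result, image = sess$image, gt = sess$gt,
         dice_initial = sess$dice_initial),
    class = "interaction_log"
  )
}

#' @export
print.interaction_log <- function(x, ...) {
  final <- x$events$dice_after[!is.na(x$events$dice_after)]
  cat(sprintf(
    "<interaction_log> %s / %s / %s: %d events, final Dice %.3f\n",
    x$subject, x$prototype, x$image_id, nrow(x$events),
    if (length(final)) final[length(final)] else x$dice_initial
  ))
  invisible(x)
}

#' Flatten an interaction log into its event table
#'
#' @param x An `interaction_log`.
#' @param ... Unused.
#' @return The event tibble with subject/prototype/image columns prepended.
#' @importFrom tibble as_tibble
#' @export
as_tibble.interaction_log <- function(x, ...) {
  dplyr::mutate(x$events, subject = x$subject, prototype = x$prototype,
                image_id = x$image_id, .before = 1)
}

session_should_stop <- function(sess) {
  pol <- sess$policy
  if (dice(as_mask(sess$result), sess$gt) >= pol$stop_dice) return(TRUE)
  err <- as_mask(sess$result) != sess$gt
  if (!any(err)) return(TRUE)
  comps <- EBImage::bwlabel(err * 1)
  max(tabulate(comps[comps > 0])) < pol$min_error_px
}

largest_error_component <- function(sess) {
  err <- as_mask(sess$result) != sess$gt
  comps <- EBImage::bwlabel(err * 1)
  sizes <- tabulate(comps[comps > 0])
  comps == which.max(sizes)
}

draw_itime <- function(pol, scale = 1) {
  rlnorm(1, pol$time_meanlog + log(scale), pol$time_sdlog)
}

# a scribble stroke inside the given component: starts at the deepest
# interior pixel and grows along nearby component pixels
robot_scribble <- function(comp, gt, pol, n) {
  d <- as.matrix(EBImage::distmap(comp * 1))
  start <- which.max(d)
  h <- nrow(comp)
  sy <- (start - 1L) %% h
  sx <- (start - 1L) %/% h
  pix <- which(comp)
  py <- (pix - 1L) %% h
  px <- (pix - 1L) %/% h
  ord <- order(pmax(abs(px - sx), abs(py - sy)))
  take <- head(ord, pol$scribble_length)
  x <- px[take]
  y <- py[take]
  labels <- ifelse(gt[cbind(y + 1L, x + 1L)], "foreground", "background")
  if (runif(1) < pol$mislabel_prob) {
    labels <- ifelse(labels == "foreground", "background", "foreground")
  }
  if (pol$jitter_sd > 0) {
    x <- pmin(pmax(x + round(rnorm(length(x), 0, pol$jitter_sd)), 0L),
              ncol(comp) - 1L)
    y <- pmin(pmax(y + round(rnorm(length(y), 0, pol$jitter_sd)), 0L),
              nrow(comp) - 1L)
  }
  out <- seed_points(x, y, labels, origin = "user_scribble", n = n)
  dplyr::distinct(out, .data$x, .data$y, .data$label, .keep_all = TRUE)
}

# ---- prototype engines -----------------------------------------------------

#' Simulate a semi-manual scribbling session
#'
#' Headless engine for the free-scribbling prototype: after the predefined
#' border background seeds, the robot repeatedly locates the largest
#' connected error component of the current segmentation versus the ground
#' truth, draws a jittered scribble inside it labelled by the ground truth
#' (mislabelled with the policy's probability), and triggers a new GrowCut
#' run over the enlarged seed set. Sessions end at the policy's Dice
#' threshold, when no error component of the policy's minimum size remains,
#' or when the interaction budget is exhausted. The run is deterministic
#' given the policy seed.
#'
#' @param image Grayscale image matrix.
#' @param gt Ground-truth foreground mask.
#' @param policy A [robot_policy()].
#' @param subject,image_id Identifiers stamped on the log.
#' @return An `interaction_log`.
#' @export
run_semi_manual <- function(image, gt, policy = robot_policy(),
                            subject = "s1", image_id = "img") {
  withr::with_seed(policy$seed, {
    init <- border_background_seeds(image, policy$border_spacing)
    sess <- session_start(image, gt, "semi_manual", policy, init,
                          subject, image_id)
    for (i in seq_len(policy$budget)) {
      if (session_should_stop(sess)) break
      if (length(sess$batches) > 0 && runif(1) < policy$undo_prob) {
        session_undo(sess, draw_itime(policy, 0.4))
        next
      }
      comp <- largest_error_component(sess)
      batch <- robot_scribble(comp, gt, policy, sess$n + 1L)
      session_commit(sess, batch, "add_scribble", draw_itime(policy))
    }
    session_finish(sess, draw_itime(policy, 0.3))
  })
}

#' The four candidate labelings of the guided prototype
#'
#' Runs one GrowCut segmentation per possible labelling of the two proposed
#' seed locations, in the fixed order (bg, bg), (bg, fg), (fg, bg),
#' (fg, fg), each on the previous seed set plus the two new seeds.
#'
#' @param image Grayscale image matrix.
#' @param seeds_prev Seed tibble accumulated so far.
#' @param p1,p2 The two proposed positions, each `c(x, y)` (0-based);
#'   must differ.
#' @param n Interaction index stamped on the new seeds.
#' @return A list of four `growcut_result` objects, named `"bb"`, `"bf"`,
#'   `"fb"`, `"ff"`.
#' @export
guided_options <- function(image, seeds_prev, p1, p2, n = 1L) {
  stopifnot(!identical(as.integer(p1), as.integer(p2)))
  schemes <- list(bb = c("background", "background"),
                  bf = c("background", "foreground"),
                  fb = c("foreground", "background"),
                  ff = c("foreground", "foreground"))
  lapply(schemes, function(sc) {
    batch <- seed_points(c(p1[1], p2[1]), c(p1[2], p2[2]), sc,
                         origin = "system_suggested", n = n)
    growcut(image, dplyr::bind_rows(seeds_prev, batch))
  })
}

#' Simulate a guided menu-driven session
#'
#' Headless engine for the guided prototype: the system is initialised with
#' the border background seeds plus one foreground seed at the ground-truth
#' centroid (the prototype needs a few fixed seeds to produce a non-empty
#' first segmentation). Each iteration proposes the two pixels with the most
#' label changes in the previous run, presents the four possible labelings
#' of those two points, and the robot picks the one matching the ground
#' truth at both positions (with the policy's mislabel probability it picks
#' a wrong option instead).
#'
#' @inheritParams run_semi_manual
#' @return An `interaction_log`.
#' @export
run_guided <- function(image, gt, policy = robot_policy(),
                       subject = "s1", image_id = "img") {
  withr::with_seed(policy$seed, {
    centroid <- round(c(mean(which(gt, arr.ind = TRUE)[, 2]),
                        mean(which(gt, arr.ind = TRUE)[, 1]))) - 1
    init <- dplyr::bind_rows(
      border_background_seeds(image, policy$border_spacing),
      seed_points(centroid[1], centroid[2], "foreground",
                  origin = "border_init", n = 0L)
    )
    sess <- session_start(image, gt, "guided", policy, init,
                          subject, image_id)
    for (i in seq_len(policy$budget)) {
      if (session_should_stop(sess)) break
      locs <- max_change_locations(sess$result$changes, k = 2L,
                                   mask = as_mask(sess$result))
      if (nrow(locs) < 2) break
      p1 <- c(locs$x[1], locs$y[1])
      p2 <- c(locs$x[2], locs$y[2])
      opts <- guided_options(image, sess$seeds, p1, p2, n = sess$n + 1L)
      truth <- c(ifelse(gt[p1[2] + 1, p1[1] + 1], "f", "b"),
                 ifelse(gt[p2[2] + 1, p2[1] + 1], "f", "b"))
      correct <- paste0(truth[1], truth[2])
      choice <- if (runif(1) < policy$mislabel_prob) {
        sample(setdiff(names(opts), correct), 1)
      } else {
        correct
      }
      labels <- c(ifelse(substr(choice, 1, 1) == "f", "foreground", "background"),
                  ifelse(substr(choice, 2, 2) == "f", "foreground", "background"))
      batch <- seed_points(c(p1[1], p2[1]), c(p1[2], p2[2]), labels,
                           origin = "system_suggested", n = sess$n + 1L)
      extra <- policy$comp_time_per_iter *
        sum(vapply(opts, function(o) o$iterations, numeric(1)))
      chosen <- opts[[choice]]
      chosen$seeds <- NULL
      session_commit(sess, batch, "choose_option", draw_itime(policy),
                     extra_ctime = extra, result = chosen)
      ev <- sess$events[[length(sess$events)]]
      ev$payload$option <- choice
      sess$events[[length(sess$events)]] <- ev
    }
    session_finish(sess, draw_itime(policy, 0.3))
  })
}

#' Simulate a joint (seed toggling) session
#'
#' Headless engine for the joint prototype: each round, an influence map
#' built from the image gradient, the previous run's label changes and the
#' contour proximity proposes `j` spread-out seed locations, automatically
#' labelled by the current mask. The robot toggles every suggested seed
#' whose automatic label disagrees with the ground truth (each needed toggle
#' is missed with the policy's mislabel probability), occasionally adds a
#' long-press seed at the largest error component, and then commits the
#' round via the new-points action, which unions the suggestions into the
#' seed set and re-segments.
#'
#' @inheritParams run_semi_manual
#' @return An `interaction_log`.
#' @export
run_joint <- function(image, gt, policy = robot_policy(),
                      subject = "s1", image_id = "img") {
  withr::with_seed(policy$seed, {
    init <- border_background_seeds(image, policy$border_spacing)
    sess <- session_start(image, gt, "joint", policy, init,
                          subject, image_id)
    for (i in seq_len(policy$budget)) {
      if (session_should_stop(sess)) break
      mask <- as_mask(sess$result)
      map <- influence_map(image, sess$result$changes, mask)
      sugg <- suggest_seeds(map, mask, j = policy$j, n = sess$n + 1L)
      sugg$value <- NULL
      # robot toggles disagreeing suggestions
      for (k in seq_len(nrow(sugg))) {
        truth <- ifelse(gt[sugg$y[k] + 1, sugg$x[k] + 1],
                        "foreground", "background")
        if (sugg$label[k] != truth && runif(1) >= policy$mislabel_prob) {
          sugg$label[k] <- truth
          session_push_event(sess, "toggle_label", draw_itime(policy, 0.25),
                             0, NA_real_,
                             list(x = sugg$x[k], y = sugg$y[k],
                                  label = truth))
        }
      }
      batch <- sugg
      err <- mask != gt
      if (any(err) && runif(1) < policy$long_press_prob) {
        comps <- EBImage::bwlabel(err * 1)
        sizes <- tabulate(comps[comps > 0])
        comp <- comps == which.max(sizes)
        d <- as.matrix(EBImage::distmap(comp * 1))
        at <- which.max(d)
        lx <- (at - 1L) %/% nrow(comp)
        ly <- (at - 1L) %% nrow(comp)
        lp <- long_press_seed(mask, lx, ly, n = sess$n + 1L)
        provisional <- dplyr::bind_rows(batch, lp)
        trans <- growcut(image, dplyr::bind_rows(sess$seeds, provisional))
        session_push_event(
          sess, "long_press", draw_itime(policy, 0.6),
          policy$comp_time_per_iter * trans$iterations,
          dice(as_mask(trans), gt), list(seeds = provisional)
        )
        batch <- provisional
      }
      session_commit(sess, batch, "new_points", draw_itime(policy, 0.5))
    }
    session_finish(sess, draw_itime(policy, 0.3))
  })
}

#' Replay an interaction log through the segmentation engine
#'
#' Reconstructs the cumulative seed set from the logged events and re-runs
#' the (deterministic) GrowCut segmentation at every event that triggered
#' one, recomputing the Dice value that was recorded live. A log is
#' consistent iff every replayed Dice equals the recorded one.
#'
#' @param log An `interaction_log`.
#' @param image,gt Image and ground truth; default to the ones carried by
#'   the log (needed when a log was read back from disk).
#' @return A tibble with `event`, `event_type`, `dice_recorded`,
#'   `dice_replayed`.
#' @export
replay_log <- function(log, image = log$image, gt = log$gt) {
  stopifnot(inherits(log, "interaction_log"))
  init <- dplyr::filter(log$seeds, .data$n == 0L)
  seeds <- init
  batches <- list()
  results <- list(growcut(image, seeds))
  out <- list()
  for (i in seq_len(nrow(log$events))) {
    type <- log$events$event_type[i]
    payload <- log$events$payload[[i]]
    rec <- log$events$dice_after[i]
    if (type %in% c("add_scribble", "choose_option", "new_points")) {
      batch <- payload$seeds
      batches[[length(batches) + 1L]] <- batch
      seeds <- dplyr::bind_rows(seeds, batch)
      res <- growcut(image, seeds)
      results[[length(results) + 1L]] <- res
      d <- dice(as_mask(res), gt)
    } else if (type == "long_press") {
      res <- growcut(image, dplyr::bind_rows(seeds, payload$seeds))
      d <- dice(as_mask(res), gt)
    } else if (type == "undo") {
      if (length(batches) > 0) {
        k <- length(batches)
        seeds <- dplyr::anti_join(seeds, batches[[k]],
                                  by = c("x", "y", "label", "origin", "n"))
        batches[[k]] <- NULL
        results[[length(results)]] <- NULL
      }
      d <- dice(as_mask(results[[length(results)]]), gt)
    } else {
      d <- NA_real_
    }
    out[[i]] <- tibble::tibble(event = i, event_type = type,
                               dice_recorded = rec, dice_replayed = d)
  }
  dplyr::bind_rows(out)
}

# ---- log serialisation -----------------------------------------------------

#' Read and write interaction logs as JSON lines
#'
#' One JSON record per line: a header with the session identifiers followed
#' by the events, with seed batches inlined. Images, ground truth and the
#' final automaton state are not serialised; [replay_log()] accepts them
#' explicitly for logs read back from disk.
#'
#' @param log An `interaction_log`.
#' @param path File path.
#' @return `write_log()` returns `path` invisibly; `read_log()` an
#'   `interaction_log` (without image/ground-truth matrices).
#' @name log_io
NULL

#' @rdname log_io
#' @export
write_log <- function(log, path) {
  header <- list(type = "header", subject = log$subject,
                 prototype = log$prototype, image_id = log$image_id,
                 dice_initial = log$dice_initial,
                 init_seeds = dplyr::filter(log$seeds, .data$n == 0L))
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, na = "null")
  for (i in seq_len(nrow(log$events))) {
    e <- as.list(log$events[i, setdiff(names(log$events), "payload")])
    e$type <- "event"
    e$payload <- log$events$payload[[i]]
    lines <- c(lines, jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                       na = "null"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname log_io
#' @export
read_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  init <- tibble::as_tibble(header$init_seeds)
  init$x <- as.integer(init$x)
  init$y <- as.integer(init$y)
  init$n <- as.integer(init$n)
  events <- lapply(lines[-1], function(l) {
    e <- jsonlite::fromJSON(l)
    payload <- e$payload
    if (!is.null(payload$seeds)) {
      s <- tibble::as_tibble(payload$seeds)
      s$x <- as.integer(s$x)
      s$y <- as.integer(s$y)
      s$n <- as.integer(s$n)
      payload$seeds <- s
    }
    tibble::tibble(
      n = as.integer(e$n), event_type = e$event_type, t_wall = e$t_wall,
      interaction_time = e$interaction_time,
      computation_time = e$computation_time,
      dice_after = if (is.null(e$dice_after)) NA_real_ else e$dice_after,
      payload = list(payload)
    )
  })
  events <- dplyr::bind_rows(events)
  seeds <- dplyr::bind_rows(
    init,
    dplyr::bind_rows(lapply(events$payload[events$event_type %in%
      c("add_scribble", "choose_option", "new_points")],
      function(p) p$seeds))
  )
  structure(
    list(subject = header$subject, prototype = header$prototype,
         image_id = header$image_id, events = events, seeds = seeds,
         result = NULL, image = NULL, gt = NULL,
         dice_initial = header$dice_initial),
    class = "interaction_log"
  )
}
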