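#' Default mapping from latent usability to a robot policy
#'
#' The cohort generator draws one latent usability level `u` in
#' `[0.15, 0.95]` per sample (subject-prototype pair) and derives the robot
#' user from it: higher `u` means steadier seed placement, fewer label
#' mistakes, fewer undos, faster interactions and a more ambitious stopping
#' Dice, so log efficiency carries the signal that the prediction pipeline
#' later tries to recover.
#'
#' @param u Latent usability in `[0, 1]`.
#' @param seed Session RNG seed.
#' @return A [robot_policy()].
#' @export
policy_from_usability <- function(u, seed = 1L) {
  robot_policy(
    scribble_length = 6L,
    jitter_sd = 0.4 + 1.6 * (1 - u),
    mislabel_prob = 0.2 * (1 - u),
    time_meanlog = log(1.2) + 1.2 * (1 - u),
    time_sdlog = 0.35,
    undo_prob = 0.12 * (1 - u),
    long_press_prob = 0.15,
    budget = 20L,
    stop_dice = 0.88 + 0.10 * u,
    seed = seed
  )
}

clamp_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# SUS item responses driven by u: the latent level maps to the favourable
# response fraction q = 0.3 + 0.6 u, odd (positive) items aim at 4q, even
# (negative) items mirror it, so the score is approximately 30 + 60 u
sus_response_from_usability <- function(u, noise_sd = 0.4) {
  q <- 4 * (0.3 + 0.6 * u)
  item <- 1:10
  target <- ifelse(item %% 2 == 1, q, 4 - q)
  noise <- if (noise_sd > 0) rnorm(10, 0, noise_sd) else 0
  tibble::tibble(item = item, value = clamp_round(target + noise, 0L, 4L))
}

# AttrakDiff-2 item responses: each group has its own affine link from u to
# the 1..7 scale (pragmatic quality reacts most strongly)
attrak_links <- list(
  "PQ" = function(u) 2.4 + 3.8 * u,
  "ATT" = function(u) 2.5 + 3.6 * u,
  "HQ-I" = function(u) 2.6 + 3.4 * u,
  "HQ-S" = function(u) 2.7 + 3.2 * u
)

attrak_response_from_usability <- function(u, noise_sd = 0.5) {
  dplyr::bind_rows(lapply(names(attrak_links), function(g) {
    target <- attrak_links[[g]](u)
    noise <- if (noise_sd > 0) rnorm(7, 0, noise_sd) else 0
    tibble::tibble(group = g, item = 1:7,
                   value = clamp_round(target + noise, 1L, 7L))
  }))
}

#' Simulate a full usability study cohort
#'
#' Emulates the two-study design: study-1 subjects segment every recorded
#' image with both the semi-manual and the guided prototype (in randomised
#' image order per task), study-2 subjects use the joint prototype. Each
#' subject first segments a practice image of medium complexity that is
#' excluded from the recorded logs. One latent usability level `u` is drawn
#' per sample (subject-prototype) and drives both the robot user
#' ([policy_from_usability()]) and the questionnaire item responses through
#' monotone links with item noise — so the questionnaire scores are
#' learnable from the logs. With the defaults (10, 11, `m = 3`) the cohort
#' has `10 * 2 + 11 = 31` samples.
#'
#' @param n_subjects_a Study-1 subjects (semi-manual + guided).
#' @param n_subjects_b Study-2 subjects (joint).
#' @param m Number of recorded images per task.
#' @param image_size `c(w, h)` of the synthetic images.
#' @param complexities Boundary roughness of the `m` recorded images
#'   (recycled/truncated to length `m`).
#' @param noise_sd,contrast Passed to [make_synthetic_image()].
#' @param policy_sampler Function `(u, seed)` returning a [robot_policy()].
#' @param sus_noise_sd,attrak_noise_sd Item noise of the response model;
#'   zero makes the questionnaire scores a deterministic monotone function
#'   of `u`.
#' @param run_practice Whether to simulate the (unrecorded) practice image.
#' @param seed Integer master seed; every drawn quantity derives from it.
#' @return A list of class `usability_cohort`: `logs` (tibble with one row
#'   per sample-image, log objects in a list column), `manifest` (one row
#'   per sample: ids, `u`, questionnaire scores), `responses` (item-level
#'   SUS and AttrakDiff-2 tibbles) and `images`.
#' @export
simulate_cohort <- function(n_subjects_a = 10L, n_subjects_b = 11L, m = 3L,
                            image_size = c(40L, 40L),
                            complexities = c(0.2, 0.5, 0.8),
                            noise_sd = 0.10, contrast = 0.35,
                            policy_sampler = policy_from_usability,
                            sus_noise_sd = 0.4, attrak_noise_sd = 0.5,
                            run_practice = TRUE, seed = 1L) {
  stopifnot(m >= 1, n_subjects_a + n_subjects_b >= 1)
  complexities <- rep_len(complexities, m)
  withr::with_seed(as.integer(seed), {
    images <- lapply(seq_len(m), function(k) {
      make_synthetic_image(complexities[k], noise_sd, image_size,
                           seed = sample.int(2^31 - 1, 1),
                           contrast = contrast)
    })
    names(images) <- paste0("img", seq_len(m))
    practice <- make_synthetic_image(0.5, noise_sd, image_size,
                                     seed = sample.int(2^31 - 1, 1),
                                     contrast = contrast)

    samples <- dplyr::bind_rows(
      tidyr::expand_grid(
        subject = sprintf("a%02d", seq_len(n_subjects_a)),
        prototype = c("semi_manual", "guided")
      ),
      tibble::tibble(subject = sprintf("b%02d", seq_len(n_subjects_b)),
                     prototype = "joint")
    )
    samples$sample_id <- paste(samples$subject, samples$prototype, sep = "/")
    samples$u <- runif(nrow(samples), 0.15, 0.95)

    engine <- function(prototype) {
      switch(prototype, semi_manual = run_semi_manual, guided = run_guided,
             joint = run_joint)
    }

    logs <- list()
    sus_items <- list()
    attrak_items <- list()
    manifest <- list()
    for (i in seq_len(nrow(samples))) {
      s <- samples[i, ]
      run <- engine(s$prototype)
      if (run_practice) {
        run(practice$image, practice$mask,
            policy_sampler(s$u, sample.int(2^31 - 1, 1)),
            subject = s$subject, image_id = "practice")
      }
      order_k <- sample.int(m)
      logs[[i]] <- tibble::tibble(
        sample_id = s$sample_id, subject = s$subject,
        prototype = s$prototype, image_id = names(images)[order_k],
        log = lapply(order_k, function(k) {
          run(images[[k]]$image, images[[k]]$mask,
              policy_sampler(s$u, sample.int(2^31 - 1, 1)),
              subject = s$subject, image_id = names(images)[k])
        })
      )
      sus <- sus_response_from_usability(s$u, sus_noise_sd)
      att <- attrak_response_from_usability(s$u, attrak_noise_sd)
      sus_items[[i]] <- dplyr::mutate(sus, sample_id = s$sample_id,
                                      .before = 1)
      attrak_items[[i]] <- dplyr::mutate(att, sample_id = s$sample_id,
                                         .before = 1)
      scores <- attrakdiff_scores(dplyr::mutate(att, subject = s$sample_id))
      manifest[[i]] <- dplyr::bind_cols(
        s, tibble::tibble(SUS = sus_score(sus$value)), scores
      )
    }

    structure(
      list(
        logs = dplyr::bind_rows(logs),
        manifest = dplyr::bind_rows(manifest),
        responses = list(sus = dplyr::bind_rows(sus_items),
                         attrakdiff = dplyr::bind_rows(attrak_items)),
        images = c(images, list(practice = practice)),
        seed = seed
      ),
      class = "usability_cohort"
    )
  })
}

#' @export
print.usability_cohort <- function(x, ...) {
  cat(sprintf(
    "<usability_cohort> %d samples (%d logs), prototypes: %s\n",
    nrow(x$manifest), nrow(x$logs),
    paste(unique(x$manifest$prototype), collapse = ", ")
  ))
  invisible(x)
}
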