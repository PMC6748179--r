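# Shared, lazily-built simulation fixtures. The heavyweight cohorts are
# constructed once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# the study-sized cohort: 10 x 2 + 11 = 31 samples under default conditions
cohort31 <- function() {
  fixture("cohort31", simulate_cohort(seed = 414))
}

features31 <- function() {
  fixture("features31", log_feature_table(cohort31()))
}

# the large synthetic cohort for the parameter-recovery experiments:
# 64 * 2 + 72 = 200 samples
cohort200 <- function() {
  fixture("cohort200", simulate_cohort(n_subjects_a = 64, n_subjects_b = 72,
                                       seed = 2020))
}

features200 <- function() {
  fixture("features200", log_feature_table(cohort200()))
}

model200 <- function() {
  fixture("model200", train_usability_model(features200(),
                                            cohort200()$manifest,
                                            grid = demo_gbrf_grid(),
                                            seed = 2020))
}

# a tiny cohort for structural tests
cohort_small <- function() {
  fixture("cohort_small",
          simulate_cohort(n_subjects_a = 2, n_subjects_b = 1, m = 2,
                          image_size = c(32, 32), seed = 77))
}

# hand-assembled interaction log with fully controlled events, for exact
# feature arithmetic
make_test_log <- function(events, seeds, image, gt, result = NULL,
                          prototype = "semi_manual", dice_initial = 0) {
  if (is.null(result)) result <- growcut(image, seeds)
  structure(
    list(subject = "t1", prototype = prototype, image_id = "fix",
         events = events, seeds = seeds, result = result, image = image,
         gt = gt, dice_initial = dice_initial),
    class = "interaction_log"
  )
}

test_event <- function(n, type, t_wall, itime, ctime, dice, payload = NULL) {
  tibble::tibble(n = n, event_type = type, t_wall = t_wall,
                 interaction_time = itime, computation_time = ctime,
                 dice_after = dice, payload = list(payload))
}
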