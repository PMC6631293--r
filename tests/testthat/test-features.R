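# Eye, vehicle and per-event feature extraction.

gaze_fixture <- function() {
  data.frame(kind = c("fixation", "saccade", "fixation", "saccade"),
             start_ms = c(0, 200, 240, 640),
             duration_ms = c(200, 40, 400, 40),
             amplitude_deg = c(NA, 5, NA, 9))
}

test_that("eye features are arithmetic means over the window", {
  one <- data.frame(kind = "fixation", start_ms = 0, duration_ms = 300,
                    amplitude_deg = NA)
  expect_equal(compute_eye_features(one, c(0, 1000))$fixation_duration, 300)

  f <- compute_eye_features(gaze_fixture(), c(0, 1000))
  expect_equal(f$fixation_duration, 300)
  expect_equal(f$saccade_range, 7)
  expect_true(is.na(f$pupil_variability))

  empty <- compute_eye_features(gaze_fixture(), c(5000, 6000))
  expect_true(is.na(empty$fixation_duration))
  expect_true(is.na(empty$saccade_range))
})

test_that("vehicle features use trapezoidal weighting and finite differences", {
  const <- data.frame(time_s = 0:9, speed_kmh = rep(60, 10))
  vf <- compute_vehicle_features(const, c(0, 10))
  expect_equal(vf$avg_speed, 60)
  expect_equal(vf$mean_acceleration, 0)

  ramp <- data.frame(time_s = 0:10, speed_kmh = seq(40, 60, length.out = 11))
  expect_equal(compute_vehicle_features(ramp, c(0, 11))$avg_speed, 50)

  single <- compute_vehicle_features(data.frame(time_s = 1, speed_kmh = 55),
                                     c(0, 2))
  expect_equal(single$avg_speed, 55)
  expect_true(is.na(single$mean_acceleration))

  expect_error(compute_vehicle_features(const, c(100, 200)), "no vehicle samples")
})

test_that("zero-noise synthetic events reproduce configured state means exactly", {
  cfg <- sim_config(state_sds = matrix(0, 2, 4),
                    los_offsets = matrix(0, 4, 4),
                    duration_offsets = matrix(0, 4, 4),
                    stage_profile = c(car_following = 1, perception = 1,
                                      intention = 1, execution = 1),
                    label_noise = 0, n_drivers = 2L)
  ds <- simulate_dataset(cfg, 6, seed = 2)
  f <- extract_features(ds$sessions)
  lab <- ds$labels$hidden_state[match(f$event_id, ds$labels$event_id)]
  expected <- cfg$state_means[lab + 1L, ]
  got <- as.matrix(f[, feature_names4])
  expect_lt(max(abs(got - expected)), 1e-9)
  expect_true(all(f$complete == 1L))
})

test_that("extraction is deterministic and permutation-stable", {
  ds <- simulate_dataset(sim_config(n_drivers = 2L), 6, seed = 42)
  f1 <- extract_features(ds$sessions)
  f2 <- extract_features(ds$sessions)
  expect_identical(f1, f2)
  set.seed(1)
  shuffled <- ds$sessions[sample(nrow(ds$sessions)), ]
  expect_identical(extract_features(shuffled), f1)
})

test_that("a stage with an empty gaze stream is flagged incomplete", {
  ds <- simulate_dataset(sim_config(n_drivers = 1L), 2, seed = 3)
  sess <- ds$sessions
  drop <- sess$event_id == "ev0001" & sess$stage == "intention" &
    sess$stream_type %in% c("fixation", "saccade")
  f <- extract_features(sess[!drop, ])
  row <- f[f$event_id == "ev0001" & f$stage == "intention", ]
  expect_identical(row$complete, 0L)
  expect_true(is.na(row$fixation_duration_ms))
  # other rows unaffected
  expect_true(all(f$complete[!(f$event_id == "ev0001" &
                                 f$stage == "intention")] == 1L))
})

test_that("event aggregation averages the four stage rows", {
  ds <- simulate_dataset(sim_config(n_drivers = 1L), 2, seed = 4)
  f <- extract_features(ds$sessions)
  agg <- aggregate_event_features(f)
  expect_identical(nrow(agg), 2L)
  manual <- colMeans(f[f$event_id == "ev0001", feature_names4])
  expect_equal(unlist(agg[agg$event_id == "ev0001", feature_names4]),
               manual)
})
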