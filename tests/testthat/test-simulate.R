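# Synthetic lane-change session generator.

test_that("state chains respect absorbing and stochastic-matrix contracts", {
  expect_identical(simulate_state_sequence(diag(2), c(1, 0), 50, seed = 1),
                   rep(0L, 50L))
  expect_error(simulate_state_sequence(matrix(c(0.9, 0.3, 0.2, 0.8), 2), c(1, 0), 5),
               "row-stochastic")
})

test_that("long chains reproduce the transition matrix and its occupancy", {
  s <- simulate_state_sequence(published_A, published_pi, 1e5, seed = 3)
  emp <- prop.table(table(factor(s[-length(s)], 0:1),
                          factor(s[-1L], 0:1)), margin = 1L)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(published_A))), 0.01)
  expect_lt(abs(mean(s == 0L) - 0.5066), 0.01)
})

test_that("R-R series are moment-matched, clipped, and reproducible", {
  rr0 <- simulate_rr_series(800, 0, 10, seed = 1)
  expect_identical(rr0$intervals, rep(800, 10L))

  rr <- simulate_rr_series(800, 50, 5000, seed = 11)
  expect_lt(abs(sd(rr$intervals) - 50), 2)
  expect_gte(min(rr$intervals), 300)
  expect_lte(max(rr$intervals), 2000)
  expect_identical(rr$intervals,
                   simulate_rr_series(800, 50, 5000, seed = 11)$intervals)
  expect_error(simulate_rr_series(800, 50, 1), ">= 2")
  expect_error(simulate_rr_series(250, 50, 10), "\\[300, 2000\\]")
})

test_that("gaze streams alternate, stay ordered, and match configured moments", {
  cfg0 <- sim_config(state_sds = matrix(0, 2, 4))
  g <- simulate_gaze_stream(0, cfg0, window_ms = 2000, seed = 1)
  expect_true(all(g$duration_ms[g$kind == "fixation"] == 250))
  expect_true(all(diff(g$start_ms) > 0))
  expect_true(all(g$kind[seq(1L, nrow(g), by = 2L)] == "fixation"))
  expect_true(all(rle(g$kind)$lengths == 1L))

  cfg <- sim_config()
  means <- vapply(1:300, function(i) {
    gg <- simulate_gaze_stream(1, cfg, window_ms = 4000, seed = i)
    mean(gg$duration_ms[gg$kind == "fixation"])
  }, 1)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - cfg$state_means["dangerous", 1L]), 3 * se)

  expect_error(simulate_gaze_stream(0, cfg, window_ms = 10), "window shorter")
})

test_that("invalid configs fail with the offending fields listed", {
  expect_error(sim_config(label_noise = 1.5), "label_noise")
  expect_error(sim_config(transition_matrix = matrix(c(0.9, 0.3, 0.2, 0.7), 2)),
               "transition_matrix")
  expect_error(sim_config(state_sds = rbind(c(-1, 1, 1, 1), rep(1, 4))),
               "state_sds")
})

test_that("datasets are deterministic and label noise behaves as configured", {
  cfg <- sim_config(n_drivers = 3L)
  d1 <- simulate_dataset(cfg, 12, seed = 42)
  d2 <- simulate_dataset(cfg, 12, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  l1 <- tempfile(fileext = ".csv"); l2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1, l1)
  write_dataset(d2, f2, l2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(l1), readLines(l2))

  d0 <- simulate_dataset(sim_config(label_noise = 0, n_drivers = 2L), 20, seed = 7)
  expect_identical(d0$labels$perception_label, d0$labels$hidden_state)
  dn <- simulate_dataset(sim_config(label_noise = 1, n_drivers = 2L), 20, seed = 7)
  expect_identical(dn$labels$perception_label, 1L - dn$labels$hidden_state)
})

test_that("generated feature targets match configured means within 3 SE", {
  cfg <- sim_config(n_drivers = 10L)
  ds <- simulate_dataset(cfg, 1000, seed = 13)
  lab <- ds$labels$hidden_state[match(ds$truth$event_id, ds$labels$event_id)]
  # car-following rows of safe events under LOS I / first duration bin:
  # target mean is exactly the configured safe state mean
  sess1 <- unique(ds$sessions[, c("event_id", "los", "duration_bin")])
  cond <- sess1[match(ds$truth$event_id, sess1$event_id), ]
  pick <- lab == 0L & ds$truth$stage == "car_following" &
    cond$los == "I" & cond$duration_bin == "lt40"
  for (k in seq_along(feature_names4)) {
    vals <- ds$truth[[feature_names4[k]]][pick]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - cfg$state_means["safe", k]), 3 * se)
  }
})

test_that("synthetic ECG places R bumps at the requested beat times", {
  ecg <- simulate_ecg(c(800, 820, 790), fs = 250)
  expect_identical(ecg$peak_times_ms, cumsum(c(800, 820, 790)))
  # nearest grid sample can sit up to half a sample off the true peak
  idx <- round(ecg$peak_times_ms / 4) + 1L
  expect_true(all(ecg$mv[idx] > 0.95))
})
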