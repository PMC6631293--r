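#' Configuration for the lane-change session simulator
#'
#' Builds and validates the generative settings used by [simulate_dataset()]:
#' a two-state (safe/dangerous) Markov chain over successive lane-change
#' events, and state- and condition-dependent emission distributions for the
#' four observed indicators (mean fixation duration, mean saccade amplitude,
#' SDNN of the R-R intervals, and average vehicle speed).
#'
#' The defaults encode the study conditions the package targets: event-level
#' risk dynamics with strong persistence in both states, roughly 3-pooled-SD
#' separation between the safe and dangerous emission means on every
#' indicator, four level-of-service (LOS) classes I-IV and four
#' driving-duration bins with additive mean shifts following the qualitative
#' trends seen in field data (fixation duration and saccade range grow with
#' congestion up to saturation then contract; SDNN declines with both
#' congestion and accumulated driving time; speed falls with congestion),
#' and a 5% chance that a driver's self-reported perception label disagrees
#' with the hidden state.
#'
#' @param transition_matrix 2x2 row-stochastic matrix of event-to-event risk
#'   transitions (row/col order: safe, dangerous).
#' @param initial_dist length-2 initial state distribution.
#' @param state_means,state_sds 2x4 numeric matrices (rows safe, dangerous;
#'   columns fixation_duration_ms, saccade_range_deg, sdnn_ms, avg_speed_kmh)
#'   of emission means and between-event SDs in natural units.
#' @param los_offsets,duration_offsets 4x4 numeric matrices of additive mean
#'   shifts, rows LOS I-IV (resp. duration bins <40, 40-80, 80-120, >120 min),
#'   columns as in `state_means`.
#' @param stage_profile named length-4 vector of relative activity
#'   multipliers for the car_following, perception, intention and execution
#'   stages; each scales the dangerous-minus-safe mean displacement in that
#'   stage.
#' @param label_noise probability in \[0,1\] that a perception label flips.
#' @param rr_mean_ms mean R-R interval in milliseconds.
#' @param event_length_ms total duration of one lane-change event.
#' @param stage_proportions length-4 vector of stage duration shares.
#' @param n_drivers number of drivers the events are distributed over; each
#'   driver's events form one Markov chain.
#' @param speed_ar,speed_walk_frac AR(1) coefficient and innovation scale
#'   (as a fraction of the state speed SD) of the within-stage speed walk.
#' @param seed default integer seed used when callers do not pass one.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(label_noise = 0)
#' cfg$transition_matrix
sim_config <- function(transition_matrix = matrix(c(0.7529, 0.2471,
                                                    0.2537, 0.7463),
                                                  2, 2, byrow = TRUE),
                       initial_dist = c(0.8584, 0.1416),
                       state_means = rbind(safe = c(250, 4, 60, 55),
                                           dangerous = c(400, 8, 35, 65)),
                       state_sds = rbind(safe = c(40, 1.2, 7, 3),
                                         dangerous = c(40, 1.2, 7, 3)),
                       los_offsets = rbind(I = c(0, 0, 0, 0),
                                           II = c(15, 0.3, -2, -8),
                                           III = c(30, 0.6, -4, -16),
                                           IV = c(10, -0.3, -2, -24)),
                       duration_offsets = rbind(lt40 = c(0, 0, 0, 0),
                                                `40_80` = c(8, 0.2, -2, -1),
                                                `80_120` = c(16, 0.4, -4, -2),
                                                gt120 = c(24, 0.6, -6, -3)),
                       stage_profile = c(car_following = 0.7, perception = 0.9,
                                         intention = 1.2, execution = 1.1),
                       label_noise = 0.05,
                       rr_mean_ms = 800,
                       event_length_ms = 60000,
                       stage_proportions = c(0.4, 0.2, 0.2, 0.2),
                       n_drivers = 25L,
                       speed_ar = 0.9,
                       speed_walk_frac = 0.3,
                       seed = 1L) {
  transition_matrix <- as.matrix(transition_matrix)
  state_means <- as.matrix(state_means)
  state_sds <- as.matrix(state_sds)
  los_offsets <- as.matrix(los_offsets)
  duration_offsets <- as.matrix(duration_offsets)

  bad <- character(0)
  if (!is_stochastic_matrix(transition_matrix, tol = 1e-12) ||
      nrow(transition_matrix) != 2L) {
    bad <- c(bad, "transition_matrix (rows must sum to 1 +/- 1e-12, 2x2, non-negative)")
  }
  if (length(initial_dist) != 2L || any(initial_dist < 0) ||
      abs(sum(initial_dist) - 1) > 1e-9) {
    bad <- c(bad, "initial_dist (length-2 probability vector)")
  }
  if (!identical(dim(state_means), c(2L, 4L))) bad <- c(bad, "state_means (2x4)")
  if (!identical(dim(state_sds), c(2L, 4L)) || any(state_sds < 0)) {
    bad <- c(bad, "state_sds (2x4, all >= 0)")
  }
  if (!identical(dim(los_offsets), c(4L, 4L))) bad <- c(bad, "los_offsets (4x4)")
  if (!identical(dim(duration_offsets), c(4L, 4L))) bad <- c(bad, "duration_offsets (4x4)")
  if (length(stage_profile) != 4L || any(stage_profile < 0)) {
    bad <- c(bad, "stage_profile (length-4, non-negative)")
  }
  if (!is.numeric(label_noise) || length(label_noise) != 1L ||
      label_noise < 0 || label_noise > 1) {
    bad <- c(bad, "label_noise (probability in [0,1])")
  }
  if (!is.numeric(rr_mean_ms) || rr_mean_ms < 300 || rr_mean_ms > 2000) {
    bad <- c(bad, "rr_mean_ms (within [300, 2000] ms)")
  }
  if (!is.numeric(event_length_ms) || event_length_ms <= 0) {
    bad <- c(bad, "event_length_ms (> 0)")
  }
  if (length(stage_proportions) != 4L || any(stage_proportions <= 0) ||
      abs(sum(stage_proportions) - 1) > 1e-9) {
    bad <- c(bad, "stage_proportions (length-4, positive, summing to 1)")
  }
  if (!is.numeric(n_drivers) || n_drivers < 1) bad <- c(bad, "n_drivers (>= 1)")
  if (length(bad)) {
    stop("invalid simulation config; offending fields: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }

  dimnames(state_means) <- dimnames(state_sds) <-
    list(c("safe", "dangerous"), FEATURES)
  dimnames(los_offsets) <- list(LOS_LEVELS, FEATURES)
  dimnames(duration_offsets) <- list(DURATION_BINS, FEATURES)
  names(stage_profile) <- STAGES

  structure(list(transition_matrix = transition_matrix,
                 initial_dist = initial_dist,
                 state_means = state_means,
                 state_sds = state_sds,
                 los_offsets = los_offsets,
                 duration_offsets = duration_offsets,
                 stage_profile = stage_profile,
                 label_noise = label_noise,
                 rr_mean_ms = rr_mean_ms,
                 event_length_ms = event_length_ms,
                 stage_proportions = stage_proportions,
                 n_drivers = as.integer(n_drivers),
                 speed_ar = speed_ar,
                 speed_walk_frac = speed_walk_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a hidden risk-state sequence
#'
#' Draws a two-state Markov chain: the first state from `pi`, each subsequent
#' state from the row of `A` indexed by its predecessor. States are coded
#' 0 = safe, 1 = dangerous.
#'
#' @param A 2x2 row-stochastic transition matrix.
#' @param pi length-2 initial distribution.
#' @param T number of steps (>= 1).
#' @param seed integer seed.
#' @return Integer vector of length `T` with values in \{0, 1\}.
#' @export
#' @examples
#' simulate_state_sequence(diag(2), c(1, 0), 5, seed = 1)
simulate_state_sequence <- function(A, pi, T, seed = 1L) {
  A <- as.matrix(A)
  if (!is_stochastic_matrix(A)) {
    stop("`A` must be a square row-stochastic matrix", call. = FALSE)
  }
  stopifnot_prob_vector(pi, "pi")
  if (!is.numeric(T) || T < 1) stop("`T` must be >= 1", call. = FALSE)
  T <- as.integer(T)
  with_seed(seed, {
    s <- integer(T)
    u <- stats::runif(T)
    s[1L] <- if (u[1L] < pi[1L]) 0L else 1L
    if (T > 1L) {
      for (t in 2L:T) {
        s[t] <- if (u[t] < A[s[t - 1L] + 1L, 1L]) 0L else 1L
      }
    }
    s
  })
}

# Moment-matched Gaussian draws: exact sample mean and sample SD (n-1).
moment_matched_normal <- function(n, mean, sd) {
  if (sd == 0 || n < 2L) return(rep(mean, n))
  z <- stats::rnorm(n)
  zsd <- stats::sd(z)
  if (zsd == 0) return(rep(mean, n))
  mean + sd * (z - mean(z)) / zsd
}

#' Simulate a series of R-R intervals
#'
#' Gaussian intervals moment-matched so that the sample mean equals
#' `mean_rr_ms` and the sample SD (the SDNN) equals `sdnn_target_ms`
#' exactly, then clipped to the physiologic range \[300, 2000\] ms
#' (clipping only engages for extreme settings).
#'
#' @param mean_rr_ms mean interval, in \[300, 2000\] ms.
#' @param sdnn_target_ms target sample SD (>= 0), ms.
#' @param n number of intervals (>= 2).
#' @param seed integer seed.
#' @return List of class `"rr_series"` with `intervals` (ms) and cumulative
#'   onset `times` (ms).
#' @export
#' @examples
#' rr <- simulate_rr_series(800, 50, 100, seed = 1)
#' compute_sdnn(rr)
simulate_rr_series <- function(mean_rr_ms, sdnn_target_ms, n, seed = 1L) {
  if (mean_rr_ms < 300 || mean_rr_ms > 2000) {
    stop("`mean_rr_ms` must lie in [300, 2000] ms", call. = FALSE)
  }
  if (sdnn_target_ms < 0) stop("`sdnn_target_ms` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2 (SDNN is undefined otherwise)", call. = FALSE)
  intervals <- with_seed(seed, moment_matched_normal(as.integer(n), mean_rr_ms,
                                                     sdnn_target_ms))
  intervals <- pmin(pmax(intervals, 300), 2000)
  rr_series(intervals)
}

#' @rdname simulate_rr_series
#' @param intervals numeric vector of positive R-R intervals (ms).
#' @export
rr_series <- function(intervals) {
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("R-R intervals must be finite and positive", call. = FALSE)
  }
  structure(list(intervals = as.numeric(intervals),
                 times = cumsum(as.numeric(intervals))),
            class = "rr_series")
}

# Draw one alternating fixation/saccade stream filling a window.
# Only complete events are kept; NULL when not even one fixation fits.
gaze_renewal <- function(mu_fix, sd_fix, mu_sac, sd_sac, window_ms,
                         min_fixation_ms = 50, saccade_duration_ms = 40) {
  kind <- character(0); start <- numeric(0); dur <- numeric(0); amp <- numeric(0)
  t <- 0
  repeat {
    d_fix <- max(min_fixation_ms, stats::rnorm(1L, mu_fix, sd_fix))
    if (t + d_fix > window_ms) break
    kind <- c(kind, "fixation"); start <- c(start, t); dur <- c(dur, d_fix)
    amp <- c(amp, NA_real_)
    t <- t + d_fix
    if (t + saccade_duration_ms > window_ms) break
    a <- max(0, stats::rnorm(1L, mu_sac, sd_sac))
    kind <- c(kind, "saccade"); start <- c(start, t)
    dur <- c(dur, saccade_duration_ms); amp <- c(amp, a)
    t <- t + saccade_duration_ms
  }
  if (!length(kind)) return(NULL)
  data.frame(kind = kind, start_ms = start, duration_ms = dur,
             amplitude_deg = amp)
}

#' Simulate a gaze-event stream
#'
#' Generates an alternating fixation/saccade renewal process filling a time
#' window, with fixation durations and saccade amplitudes drawn from the
#' configured distributions of the given risk state.
#'
#' @param state risk state, 0/"safe" or 1/"dangerous".
#' @param config a [sim_config()].
#' @param window_ms window length (> 0), ms.
#' @param seed integer seed.
#' @return data.frame with columns `kind`, `start_ms`, `duration_ms`,
#'   `amplitude_deg` (NA for fixations); start times strictly increase and
#'   kinds alternate starting with a fixation.
#' @export
simulate_gaze_stream <- function(state, config = sim_config(), window_ms,
                                 seed = 1L) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  if (window_ms <= 0) stop("`window_ms` must be > 0", call. = FALSE)
  row <- state_row(state)
  ev <- with_seed(seed, gaze_renewal(config$state_means[row, 1L],
                                     config$state_sds[row, 1L],
                                     config$state_means[row, 2L],
                                     config$state_sds[row, 2L],
                                     window_ms))
  if (is.null(ev)) {
    stop("window shorter than the minimum event duration: empty gaze stream",
         call. = FALSE)
  }
  ev
}

state_row <- function(state) {
  if (is.character(state)) {
    state <- match.arg(state, c("safe", "dangerous"))
    if (state == "dangerous") 2L else 1L
  } else {
    if (!state %in% c(0, 1)) {
      stop("`state` must be 0 (safe) or 1 (dangerous)", call. = FALSE)
    }
    as.integer(state) + 1L
  }
}

#' Simulate a synthetic single-lead ECG waveform
#'
#' Places Gaussian R-wave bumps at the cumulative times of a given R-R
#' interval train over a flat baseline, with optional additive white noise.
#' Intended for exercising R-peak detection; no P/T morphology is modelled.
#'
#' @param rr_ms numeric vector of R-R intervals (ms).
#' @param fs sampling frequency (Hz).
#' @param noise_sd SD of additive Gaussian noise (signal units; R amplitude 1).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param r_width_ms Gaussian R-wave width parameter (ms).
#' @return List with `t_ms`, `mv` (waveform), and the true `peak_times_ms`.
#' @export
simulate_ecg <- function(rr_ms, fs = 250, noise_sd = 0, seed = 1L,
                         r_width_ms = 12) {
  peaks <- cumsum(rr_ms)
  t_ms <- seq(0, max(peaks) + 400, by = 1000 / fs)
  mv <- numeric(length(t_ms))
  for (p in peaks) {
    mv <- mv + exp(-((t_ms - p)^2) / (2 * r_width_ms^2))
  }
  if (noise_sd > 0) {
    mv <- mv + with_seed(seed, stats::rnorm(length(t_ms), 0, noise_sd))
  }
  list(t_ms = t_ms, mv = mv, peak_times_ms = peaks)
}

#' Simulate a labelled lane-change session dataset
#'
#' Draws per-driver chains of hidden risk states, assigns LOS and
#' driving-duration condition labels, and emits the three raw signal streams
#' (R-R intervals, gaze events, vehicle speed) for each of the four stages of
#' every lane-change event. Perception labels equal the hidden state flipped
#' independently with probability `config$label_noise`.
#'
#' Within each stage the emitted stream is constructed so that its summary
#' feature reproduces the event's target value: R-R intervals are
#' moment-matched to the target SDNN, gaze and speed streams fluctuate around
#' the target means. Targets are the configured state means, displaced by the
#' stage activity profile and the additive LOS/duration offsets, plus a
#' between-event Gaussian deviation with the configured state SDs.
#'
#' @param config a [sim_config()].
#' @param n_events number of lane-change events (>= 1).
#' @param seed integer seed (defaults to `config$seed`).
#' @return List of class `"lane_change_dataset"` with elements
#'   `sessions` (long signal table: event_id, driver, stage, los,
#'   duration_bin, stream_type, t_ms, value, unit), `labels` (event_id,
#'   driver, hidden_state, perception_label), `truth` (per event x stage
#'   target feature values), `config`, `seed`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_drivers = 2), n_events = 6, seed = 1)
#' head(ds$labels)
simulate_dataset <- function(config = sim_config(), n_events,
                             seed = config$seed) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be built by sim_config()", call. = FALSE)
  }
  if (!is.numeric(n_events) || n_events < 1) {
    stop("`n_events` must be >= 1", call. = FALSE)
  }
  n_events <- as.integer(n_events)
  n_drivers <- min(config$n_drivers, n_events)
  per_driver <- rep(n_events %/% n_drivers, n_drivers)
  extra <- n_events %% n_drivers
  if (extra > 0) per_driver[seq_len(extra)] <- per_driver[seq_len(extra)] + 1L

  stage_ms <- config$event_length_ms * config$stage_proportions
  delta <- config$state_means["dangerous", ] - config$state_means["safe", ]

  with_seed(seed, {
    ev <- 0L
    states <- integer(n_events)
    drivers <- character(n_events)
    event_ids <- sprintf("ev%04d", seq_len(n_events))
    los_all <- sample(LOS_LEVELS, n_events, replace = TRUE)
    dur_all <- character(n_events)

    acc <- vector("list", 4L * n_events)
    truth <- vector("list", 4L * n_events)
    k <- 0L

    for (d in seq_len(n_drivers)) {
      nd <- per_driver[d]
      if (nd == 0L) next
      # per-driver hidden chain
      u <- stats::runif(nd)
      s <- integer(nd)
      s[1L] <- if (u[1L] < config$initial_dist[1L]) 0L else 1L
      if (nd > 1L) for (t in 2L:nd) {
        s[t] <- if (u[t] < config$transition_matrix[s[t - 1L] + 1L, 1L]) 0L else 1L
      }
      for (j in seq_len(nd)) {
        ev <- ev + 1L
        states[ev] <- s[j]
        drivers[ev] <- sprintf("d%02d", d)
        # driving duration accumulates within a session: bin by position
        dur_all[ev] <- DURATION_BINS[pmin(4L, 1L + ((j - 1L) * 4L) %/% max(nd, 1L))]
        id <- event_ids[ev]
        srow <- s[j] + 1L
        eps <- stats::rnorm(4L) * config$state_sds[srow, ]
        for (si in seq_along(STAGES)) {
          stage <- STAGES[si]
          mu <- config$state_means["safe", ] +
            config$stage_profile[si] * (s[j] == 1L) * delta +
            config$los_offsets[los_all[ev], ] +
            config$duration_offsets[dur_all[ev], ] + eps
          mu[2L] <- max(mu[2L], 0)   # saccade amplitude
          mu[3L] <- max(mu[3L], 0.5) # sdnn
          mu[4L] <- max(mu[4L], 1)   # speed
          t0 <- sum(stage_ms[seq_len(si - 1L)])

          n_rr <- max(2L, as.integer(round(stage_ms[si] / config$rr_mean_ms)))
          rr <- pmin(pmax(moment_matched_normal(n_rr, config$rr_mean_ms, mu[3L]),
                          300), 2000)
          gz <- gaze_renewal(mu[1L], config$state_sds[srow, 1L],
                             mu[2L], config$state_sds[srow, 2L], stage_ms[si])
          n_sp <- max(2L, as.integer(stage_ms[si] / 1000))
          wsd <- config$speed_walk_frac * config$state_sds[srow, 4L]
          v <- numeric(n_sp)
          v[1L] <- mu[4L]
          if (n_sp > 1L) {
            innov <- stats::rnorm(n_sp - 1L, 0, wsd)
            for (t in 2L:n_sp) {
              v[t] <- mu[4L] + config$speed_ar * (v[t - 1L] - mu[4L]) + innov[t - 1L]
            }
          }
          v <- pmax(v, 0)

          n_gz <- if (is.null(gz)) 0L else nrow(gz)
          k <- k + 1L
          acc[[k]] <- data.frame(
            event_id = id, driver = drivers[ev], stage = stage,
            los = los_all[ev], duration_bin = dur_all[ev],
            stream_type = c(rep("rr", n_rr),
                            if (n_gz) gz$kind,
                            rep("speed", n_sp)),
            t_ms = c(t0 + cumsum(rr),
                     if (n_gz) t0 + gz$start_ms,
                     t0 + (seq_len(n_sp) - 1L) * 1000),
            value = c(rr,
                      if (n_gz) ifelse(gz$kind == "fixation",
                                       gz$duration_ms, gz$amplitude_deg),
                      v),
            unit = c(rep("ms", n_rr),
                     if (n_gz) ifelse(gz$kind == "fixation", "ms", "deg"),
                     rep("km_h", n_sp)))
          truth[[k]] <- data.frame(event_id = id, stage = stage,
                                   fixation_duration_ms = mu[1L],
                                   saccade_range_deg = mu[2L],
                                   sdnn_ms = mu[3L], avg_speed_kmh = mu[4L])
        }
      }
    }
    sessions <- do.call(rbind, acc[seq_len(k)])
    rownames(sessions) <- NULL
    truth <- do.call(rbind, truth[seq_len(k)])
    rownames(truth) <- NULL
    flip <- stats::runif(n_events) < config$label_noise
    labels <- data.frame(event_id = event_ids, driver = drivers,
                         hidden_state = states,
                         perception_label = ifelse(flip, 1L - states, states))
    structure(list(sessions = sessions, labels = labels, truth = truth,
                   config = config, seed = as.integer(seed)),
              class = "lane_change_dataset")
  })
}

#' Read and write session/label tables
#'
#' Plain-CSV serialization of the tables produced by [simulate_dataset()].
#'
#' @param dataset a `lane_change_dataset`.
#' @param sessions_path,labels_path output CSV paths.
#' @return `write_dataset()` returns the paths invisibly; `read_sessions()`
#'   and `read_labels()` return data.frames.
#' @export
write_dataset <- function(dataset, sessions_path, labels_path) {
  utils::write.csv(dataset$sessions, sessions_path, row.names = FALSE)
  utils::write.csv(dataset$labels, labels_path, row.names = FALSE)
  invisible(c(sessions = sessions_path, labels = labels_path))
}

#' @rdname write_dataset
#' @param path a CSV path.
#' @export
read_sessions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "stage", "los", "duration_bin", "stream_type",
            "t_ms", "value", "unit")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sessions table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname write_dataset
#' @export
read_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
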