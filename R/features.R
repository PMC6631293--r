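# Eye-movement and vehicle-dynamic indicators, and the per-event, per-stage
# feature extraction over a long-format session table.

#' Eye-movement indicators over a stage window
#'
#' Mean fixation duration (ms), mean saccade amplitude (degrees) and, when
#' pupil samples are available, the standard deviation of pupil diameter
#' (mm) over the gaze events whose start time falls inside the window.
#' Missing inputs yield `NA` values (a missing-value flag), never silent
#' zeros.
#'
#' @param events data.frame of gaze events with columns `kind`
#'   ("fixation"/"saccade"), `start_ms`, `duration_ms`, `amplitude_deg`,
#'   and optionally `pupil_mm`.
#' @param window length-2 numeric, window start/end in ms.
#' @return List with `fixation_duration`, `saccade_range`,
#'   `pupil_variability`.
#' @export
compute_eye_features <- function(events, window) {
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("`window` must be an increasing (start, end) pair", call. = FALSE)
  }
  inside <- events$start_ms >= window[1L] & events$start_ms < window[2L]
  ev <- events[inside, , drop = FALSE]
  fix <- ev[ev$kind == "fixation", , drop = FALSE]
  sac <- ev[ev$kind == "saccade", , drop = FALSE]
  list(
    fixation_duration = if (nrow(fix)) mean(fix$duration_ms) else NA_real_,
    saccade_range = if (nrow(sac)) mean(sac$amplitude_deg) else NA_real_,
    pupil_variability = if (!is.null(ev$pupil_mm) &&
                            sum(is.finite(ev$pupil_mm)) >= 2L) {
      stats::sd(ev$pupil_mm[is.finite(ev$pupil_mm)])
    } else NA_real_
  )
}

#' Vehicle-dynamic indicators over a stage window
#'
#' Time-weighted (trapezoidal) mean speed, and the mean of finite-difference
#' accelerations when an acceleration channel is not supplied. A
#' single-sample window returns that sample as the average speed with the
#' acceleration flagged missing (`NA`).
#'
#' @param trace data.frame with `time_s`, `speed_kmh` and optionally
#'   `accel_ms2`; times strictly increasing, speeds >= 0.
#' @param window length-2 numeric, window start/end in seconds.
#' @return List with `avg_speed` (km/h) and `mean_acceleration` (m/s^2).
#' @export
compute_vehicle_features <- function(trace, window) {
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("`window` must be an increasing (start, end) pair", call. = FALSE)
  }
  inside <- trace$time_s >= window[1L] & trace$time_s < window[2L]
  tr <- trace[inside, , drop = FALSE]
  if (!nrow(tr)) stop("no vehicle samples fall inside the window", call. = FALSE)
  tr <- tr[order(tr$time_s), , drop = FALSE]
  v <- tr$speed_kmh
  t <- tr$time_s
  if (nrow(tr) == 1L) {
    return(list(avg_speed = v, mean_acceleration = NA_real_))
  }
  dt <- diff(t)
  avg <- sum((v[-1L] + v[-length(v)]) / 2 * dt) / sum(dt)
  acc <- if (!is.null(tr$accel_ms2) && all(is.finite(tr$accel_ms2))) {
    mean(tr$accel_ms2)
  } else {
    mean(diff(v / 3.6) / dt)
  }
  list(avg_speed = avg, mean_acceleration = acc)
}

#' Extract per-event, per-stage feature vectors from a session table
#'
#' Computes one observation row per lane-change stage of every event: the
#' four selected indicators (mean fixation duration, mean saccade range,
#' SDNN, average speed) are always attempted; extended indicators (CV,
#' LF/HF, pupil-diameter variability, mean acceleration) are filled when
#' their inputs suffice (LF/HF needs a >= 120 s R-R record and is typically
#' undefined at stage scale). Rows missing any selected indicator are
#' flagged `complete = 0` and excluded from model training by default.
#'
#' @param sessions long-format signal table as produced by
#'   [simulate_dataset()] / [read_sessions()].
#' @return data.frame with one row per event x stage: condition labels, the
#'   selected and extended features, and a `complete` flag (0/1). Rows are
#'   ordered by event id and canonical stage order, independent of the input
#'   row order.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_drivers = 1), n_events = 2, seed = 1)
#' extract_features(ds$sessions)
extract_features <- function(sessions) {
  need <- c("event_id", "stage", "los", "duration_bin", "stream_type",
            "t_ms", "value")
  miss <- setdiff(need, names(sessions))
  if (length(miss)) {
    stop("sessions table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sessions <- sessions[order(sessions$event_id, sessions$t_ms), , drop = FALSE]
  keys <- unique(sessions[, c("event_id", "stage", "los", "duration_bin",
                              intersect("driver", names(sessions))),
                          drop = FALSE])
  keys <- keys[order(keys$event_id, match(keys$stage, STAGES)), , drop = FALSE]
  grp <- split(sessions, list(sessions$event_id, sessions$stage), drop = TRUE)

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- grp[[paste(keys$event_id[i], keys$stage[i], sep = ".")]]
    rr <- g$value[g$stream_type == "rr"]
    fix <- g[g$stream_type == "fixation", , drop = FALSE]
    sac <- g[g$stream_type == "saccade", , drop = FALSE]
    pup <- g$value[g$stream_type == "pupil"]
    sp <- g[g$stream_type == "speed", , drop = FALSE]

    sdnn <- if (length(rr) >= 2L) compute_sdnn(rr) else NA_real_
    cv <- if (length(rr) >= 2L) compute_cv(rr) else NA_real_
    lf_hf <- if (length(rr) >= 2L && sum(rr) / 1000 >= 120) {
      tryCatch(compute_lf_hf(rr)$ratio, error = function(e) NA_real_)
    } else NA_real_
    fixation <- if (nrow(fix)) mean(fix$value) else NA_real_
    saccade <- if (nrow(sac)) mean(sac$value) else NA_real_
    pupil <- if (length(pup) >= 2L) stats::sd(pup) else NA_real_
    if (nrow(sp)) {
      vf <- compute_vehicle_features(
        data.frame(time_s = sp$t_ms / 1000, speed_kmh = sp$value),
        window = c(min(sp$t_ms) / 1000, max(sp$t_ms) / 1000 + 1e-9))
      avg_speed <- vf$avg_speed
      accel <- vf$mean_acceleration
    } else {
      avg_speed <- NA_real_
      accel <- NA_real_
    }
    out <- data.frame(event_id = keys$event_id[i], stage = keys$stage[i],
                      los = keys$los[i], duration_bin = keys$duration_bin[i],
                      fixation_duration_ms = fixation,
                      saccade_range_deg = saccade,
                      sdnn_ms = sdnn, avg_speed_kmh = avg_speed,
                      cv = cv, lf_hf = lf_hf, pupil_var_mm = pupil,
                      mean_accel_ms2 = accel)
    out$complete <- as.integer(all(is.finite(c(fixation, saccade, sdnn,
                                               avg_speed))))
    if ("driver" %in% names(keys)) out$driver <- keys$driver[i]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse stage rows into event-level observations
#'
#' Averages (unweighted) the complete stage rows of each event over the
#' four selected indicators; an event is flagged complete only when all
#' four stages are. These event-level vectors are the HMM observations of
#' the training pipeline.
#'
#' @param features stage-row feature table from [extract_features()].
#' @return One row per event with the four indicators, condition labels and
#'   a `complete` flag.
#' @export
aggregate_event_features <- function(features) {
  sp <- split(features, features$event_id)
  rows <- lapply(sp, function(g) {
    ok <- g$complete == 1L
    vals <- if (any(ok)) {
      colMeans(g[ok, FEATURES, drop = FALSE])
    } else {
      stats::setNames(rep(NA_real_, 4L), FEATURES)
    }
    out <- data.frame(event_id = g$event_id[1L],
                      los = g$los[1L], duration_bin = g$duration_bin[1L])
    out[FEATURES] <- as.list(vals)
    out$complete <- as.integer(sum(ok) == 4L)
    if ("driver" %in% names(g)) out$driver <- g$driver[1L]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
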