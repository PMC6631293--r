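# End-to-end orchestration: simulate -> features -> screen -> train ->
# decode -> evaluate, plus the per-stage probability report.

#' Prediction accuracy against perceived risk labels
#'
#' @param predicted,perceived equal-length label vectors (0 = safe,
#'   1 = dangerous, or the corresponding character labels).
#' @return List with `accuracy` (percent, two decimals), `confusion`
#'   (2 x 2 count matrix, predicted x perceived), `n`.
#' @export
#' @examples
#' evaluate_predictions(c(rep(1, 68), rep(0, 7)), rep(1, 75))$accuracy # 90.67
evaluate_predictions <- function(predicted, perceived) {
  predicted <- as_binary_label(predicted)
  perceived <- as_binary_label(perceived)
  if (length(predicted) != length(perceived) || !length(predicted)) {
    stop("`predicted` and `perceived` must be equal-length, non-empty",
         call. = FALSE)
  }
  acc <- round(100 * mean(predicted == perceived), 2L)
  lv <- c(0L, 1L)
  confusion <- table(factor(predicted, lv, c("safe", "dangerous")),
                     factor(perceived, lv, c("safe", "dangerous")),
                     dnn = c("predicted", "perceived"))
  list(accuracy = acc, confusion = unclass(confusion), n = length(predicted))
}

as_binary_label <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    ok <- x %in% c("safe", "dangerous")
    if (!all(ok)) stop("labels must be 'safe'/'dangerous' or 0/1", call. = FALSE)
    return(as.integer(x == "dangerous"))
  }
  if (!all(x %in% c(0, 1))) stop("labels must be 'safe'/'dangerous' or 0/1",
                                 call. = FALSE)
  as.integer(x)
}

# Seeded split of event ids, stratified by a label; returns logical
# train-mask. Train size is floor(split * n) overall, with per-stratum
# rounding balanced by largest remainders.
stratified_split <- function(labels, split, seed) {
  n <- length(labels)
  n_train <- as.integer(floor(split * n))
  strata <- split(seq_len(n), labels)
  quota <- vapply(strata, length, 1L) * split
  base <- pmin(floor(quota), vapply(strata, length, 1L))
  rem <- n_train - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      if (base[i] < length(strata[[i]])) {
        base[i] <- base[i] + 1L
        rem <- rem - 1L
      }
    }
  }
  mask <- logical(n)
  with_seed(seed, {
    for (i in seq_along(strata)) {
      pick <- sample(strata[[i]], base[i])
      mask[pick] <- TRUE
    }
  })
  mask
}

# Per-driver sequences of event-level observation rows. Returns a list of
# matrices; `runs = TRUE` breaks each driver at gaps in the original event
# order (used for gappy training subsets).
driver_sequences <- function(event_feats, features, runs = FALSE) {
  sp <- split(event_feats, event_feats$driver)
  out <- list()
  for (g in sp) {
    g <- g[order(g$event_id), , drop = FALSE]
    if (runs && !is.null(g$.pos)) {
      brk <- cumsum(c(1L, diff(g$.pos) != 1L))
    } else {
      brk <- rep(1L, nrow(g))
    }
    for (r in split(g, brk)) {
      out[[length(out) + 1L]] <- list(
        obs = as.matrix(r[, features, drop = FALSE]),
        event_id = r$event_id)
    }
  }
  out
}

#' Run the full risk-prediction pipeline on simulated sessions
#'
#' Simulates a labelled session dataset, extracts per-stage features,
#' screens them against LOS and driving duration, trains the two-state HMM
#' on event-level observations of the selected indicators (per-driver
#' chains of the training events), aligns state labels, decodes the
#' held-out events and scores them against the drivers' perception labels.
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param n_events total number of lane-change events.
#' @param split training fraction of events (stratified by perception
#'   label); the default 0.85 holds out 15% of events.
#' @param seed integer seed controlling simulation, split and fit.
#' @param features observed indicators used as HMM input.
#' @param K,structure,tol,max_iter passed to [risk_hmm()].
#' @param model_path,report_path optional output paths for the model JSON
#'   and report JSON.
#' @return List of class `"risk_report"`: `accuracy`, `confusion`,
#'   `n_train`, `n_test`, `stage_table`, `selected_features` (screen
#'   outcome on the synthetic features), `model`, `provenance`.
#' @export
run_pipeline <- function(config = sim_config(), n_events = 500L,
                         split = 0.85, seed = 42L,
                         features = FEATURES, K = 1L,
                         structure = "ergodic", tol = 1e-6, max_iter = 500L,
                         model_path = NULL, report_path = NULL) {
  if (split <= 0 || split >= 1) stop("`split` must lie in (0, 1)", call. = FALSE)
  ds <- simulate_dataset(config, n_events, seed = seed)
  feats <- extract_features(ds$sessions)
  miss <- setdiff(features, names(feats))
  if (length(miss)) {
    stop("selected feature columns missing from extracted features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  screening <- screen_features(feats)
  selected <- tryCatch(
    select_features(screening[is.finite(screening$I2), , drop = FALSE]),
    error = function(e) character(0))

  event_feats <- aggregate_event_features(feats)
  event_feats <- merge(event_feats, ds$labels[, c("event_id", "hidden_state",
                                                  "perception_label")],
                       by = "event_id", sort = TRUE)
  event_feats <- event_feats[event_feats$complete == 1L, , drop = FALSE]
  event_feats <- event_feats[order(event_feats$event_id), , drop = FALSE]
  # position of each event within its driver's session (for run-splitting)
  event_feats$.pos <- stats::ave(seq_len(nrow(event_feats)),
                                 event_feats$driver,
                                 FUN = seq_along)

  mask <- stratified_split(event_feats$perception_label, split,
                           child_seed(seed, 2L))
  train <- event_feats[mask, , drop = FALSE]
  test <- event_feats[!mask, , drop = FALSE]
  if (!nrow(test)) stop("empty test split", call. = FALSE)

  train_seqs <- driver_sequences(train, features, runs = TRUE)
  model <- risk_hmm(lapply(train_seqs, `[[`, "obs"), feature_names = features,
                    K = K, structure = structure, tol = tol,
                    max_iter = max_iter, seed = child_seed(seed, 3L))

  test_seqs <- driver_sequences(test, features, runs = FALSE)
  pred <- integer(0)
  ids <- character(0)
  for (s in test_seqs) {
    path <- viterbi(model, s$obs)
    lab <- attr(path, "labels")
    pred <- c(pred, as.integer(lab == "dangerous"))
    ids <- c(ids, s$event_id)
  }
  perceived <- test$perception_label[match(ids, test$event_id)]
  ev <- evaluate_predictions(pred, perceived)

  stage_tab <- stage_probability_table(model, feats, test_events = test$event_id,
                                       drivers = test[, c("event_id", "driver")],
                                       features = features,
                                       all_features = test)

  if (!is.null(model_path)) write_hmm_json(model, model_path)
  report <- structure(list(accuracy = ev$accuracy, confusion = ev$confusion,
                           n_train = nrow(train), n_test = nrow(test),
                           stage_table = stage_tab,
                           selected_features = selected,
                           model = model,
                           provenance = list(seed = as.integer(seed),
                                             n_events = as.integer(n_events),
                                             split = split,
                                             features = features,
                                             K = as.integer(K),
                                             structure = structure)),
                      class = "risk_report")
  if (!is.null(report_path)) write_report(report, report_path)
  report
}

#' Per-stage driving-status probability table
#'
#' Re-decodes the held-out events once per lane-change stage, substituting
#' that stage's feature rows for the event observations (the training model
#' is unchanged), then reports per stage the share of events decoded safe
#' and dangerous and the empirical transition probabilities between
#' consecutive decoded events, plus an "All" row using the event-level
#' aggregate observations. Stage rows with no decoded transitions carry NA
#' transition cells.
#'
#' @param model fitted, aligned `risk_hmm`.
#' @param stage_features per-stage feature table ([extract_features()]).
#' @param test_events event ids to include.
#' @param drivers data.frame mapping `event_id` to `driver`.
#' @param features observed indicator columns.
#' @param all_features event-level aggregate rows for the "All" row.
#' @return data.frame with columns stage, `P_safe`, `P_dangerous`,
#'   `P_s-s`, `P_s-d`, `P_d-s`, `P_d-d` (percent).
#' @export
stage_probability_table <- function(model, stage_features, test_events,
                                    drivers, features = FEATURES,
                                    all_features = NULL) {
  decode_set <- function(tbl) {
    tbl <- merge(tbl, drivers, by = "event_id", sort = TRUE)
    states <- integer(0)
    trans <- matrix(0, 2L, 2L)
    for (g in split(tbl, tbl$driver)) {
      g <- g[order(g$event_id), , drop = FALSE]
      if (!nrow(g)) next
      path <- as.integer(attr(viterbi(model, g[, features, drop = FALSE]),
                              "labels") == "dangerous")
      states <- c(states, path)
      if (length(path) > 1L) {
        for (t in seq_len(length(path) - 1L)) {
          trans[path[t] + 1L, path[t + 1L] + 1L] <-
            trans[path[t] + 1L, path[t + 1L] + 1L] + 1L
        }
      }
    }
    p_safe <- 100 * mean(states == 0L)
    row_p <- function(i) {
      tot <- sum(trans[i, ])
      if (tot == 0) c(NA_real_, NA_real_) else 100 * trans[i, ] / tot
    }
    c(p_safe, 100 - p_safe, row_p(1L), row_p(2L))
  }

  rows <- list()
  for (stage in STAGES) {
    tbl <- stage_features[stage_features$stage == stage &
                          stage_features$event_id %in% test_events &
                          stage_features$complete == 1L, , drop = FALSE]
    tbl <- tbl[, c("event_id", features), drop = FALSE]
    rows[[stage]] <- decode_set(tbl)
  }
  if (!is.null(all_features)) {
    rows[["All"]] <- decode_set(all_features[, c("event_id", features),
                                             drop = FALSE])
  }
  out <- data.frame(stage = names(rows), do.call(rbind, rows),
                    check.names = FALSE)
  names(out) <- c("stage", "P_safe", "P_dangerous", "P_s-s", "P_s-d",
                  "P_d-s", "P_d-d")
  rownames(out) <- NULL
  out
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Lane-change risk pipeline report\n")
  cat(sprintf("Events: %d train / %d test  Held-out accuracy: %.2f%%\n",
              x$n_train, x$n_test, x$accuracy))
  cat("\nConfusion (predicted x perceived):\n")
  print(x$confusion)
  cat("\nScreened-in features:",
      if (length(x$selected_features)) {
        paste(x$selected_features, collapse = ", ")
      } else "(none)", "\n")
  cat("\nPer-stage driving-status probabilities (%):\n")
  print(cbind(x$stage_table[1L], round(x$stage_table[-1L], 2L)))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `risk_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- list(accuracy = report$accuracy,
              confusion = report$confusion,
              n_train = report$n_train, n_test = report$n_test,
              stage_table = report$stage_table,
              selected_features = report$selected_features,
              provenance = report$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
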