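# Two-state hidden Markov model with Gaussian-mixture emissions:
# model constructor, log-space recursions, decoding and risk forecasting.

#' Construct a hidden Markov risk model
#'
#' Builds a `risk_hmm` object from explicit parameters. Emissions are
#' Gaussian mixtures with diagonal covariances: per state, `K` components
#' with mixing weights, mean vectors and per-feature variances.
#'
#' @param pi initial state distribution (length N, sums to 1 within 1e-9).
#' @param A N x N row-stochastic transition matrix. Under the `"left_right"`
#'   structure only self- and next-state transitions are allowed and the
#'   last state is absorbing.
#' @param means per-state component means: an N x D matrix (one component
#'   per state) or a list of N matrices (K x D each).
#' @param vars per-state diagonal variances, same shape as `means`; all
#'   entries must exceed 0.
#' @param weights list of N mixing-weight vectors (each sums to 1), or
#'   `NULL` for single-component states.
#' @param feature_names optional length-D character vector.
#' @param structure `"ergodic"` (default) or `"left_right"`.
#' @param standardization optional list with `means` and `sds` used to
#'   z-score observations before evaluating emission densities.
#' @param labels state labels, by position.
#' @return Object of class `"risk_hmm"`.
#' @export
#' @examples
#' m <- hmm_model(pi = c(0.9, 0.1),
#'                A = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
#'                means = rbind(c(0, 0), c(3, 3)),
#'                vars = rbind(c(1, 1), c(1, 1)))
#' m
hmm_model <- function(pi, A, means, vars, weights = NULL,
                      feature_names = NULL,
                      structure = c("ergodic", "left_right"),
                      standardization = NULL,
                      labels = c("safe", "dangerous")) {
  structure_kind <- match.arg(structure)
  A <- as.matrix(A)
  N <- length(pi)
  if (is.matrix(means)) means <- lapply(seq_len(N), function(j) means[j, , drop = FALSE])
  if (is.matrix(vars)) vars <- lapply(seq_len(N), function(j) vars[j, , drop = FALSE])
  means <- lapply(means, function(m) as.matrix(m))
  vars <- lapply(vars, function(v) as.matrix(v))
  D <- ncol(means[[1L]])
  if (is.null(weights)) weights <- lapply(means, function(m) rep(1 / nrow(m), nrow(m)))
  if (is.null(feature_names)) feature_names <- colnames(means[[1L]]) %||% paste0("f", seq_len(D))

  stopifnot_prob_vector(pi, "pi", tol = 1e-9)
  if (!is_stochastic_matrix(A, tol = 1e-9) || nrow(A) != N) {
    stop("`A` must be an N x N row-stochastic matrix (rows sum to 1 +/- 1e-9)",
         call. = FALSE)
  }
  if (structure_kind == "left_right") {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (!(j %in% c(i, i + 1L)) && A[i, j] > 1e-12) {
        stop("left_right structure forbids transition ", i, " -> ", j,
             call. = FALSE)
      }
    }
    if (abs(A[N, N] - 1) > 1e-9) {
      stop("left_right structure requires the last state to be absorbing",
           call. = FALSE)
    }
  }
  for (j in seq_len(N)) {
    if (abs(sum(weights[[j]]) - 1) > 1e-9 || any(weights[[j]] < 0)) {
      stop("mixture weights of state ", j, " must sum to 1", call. = FALSE)
    }
    if (!identical(dim(means[[j]]), dim(vars[[j]])) ||
        ncol(means[[j]]) != D || nrow(means[[j]]) != length(weights[[j]])) {
      stop("means/vars/weights of state ", j, " have inconsistent shapes",
           call. = FALSE)
    }
    if (any(vars[[j]] <= 0)) {
      stop("all emission variances must be positive", call. = FALSE)
    }
  }
  states <- lapply(seq_len(N), function(j) {
    list(label = labels[j], weights = as.numeric(weights[[j]]),
         means = unname(means[[j]]), vars = unname(vars[[j]]))
  })
  obj <- list(pi = as.numeric(pi), A = unname(A), states = states,
              feature_names = feature_names, structure = structure_kind,
              standardization = standardization, training = NULL)
  class(obj) <- "risk_hmm"
  obj
}

n_states <- function(model) length(model$pi)

# Coerce observations to a T x D numeric matrix in model feature order,
# then z-score with the model's stored standardization.
obs_matrix <- function(model, obs) {
  if (is.data.frame(obs)) {
    cols <- intersect(model$feature_names, names(obs))
    if (length(cols) != length(model$feature_names)) {
      stop("observations lack feature columns: ",
           paste(setdiff(model$feature_names, names(obs)), collapse = ", "),
           call. = FALSE)
    }
    obs <- as.matrix(obs[, model$feature_names, drop = FALSE])
  }
  obs <- as.matrix(obs)
  if (ncol(obs) != length(model$feature_names)) {
    stop("observations must have ", length(model$feature_names), " columns",
         call. = FALSE)
  }
  if (any(!is.finite(obs))) {
    bad <- which(!stats::complete.cases(obs))
    stop("non-finite observation at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  std <- model$standardization
  if (!is.null(std)) {
    obs <- sweep(sweep(obs, 2L, std$means, "-"), 2L, std$sds, "/")
  }
  obs
}

# Per-component log-densities: list over states of T x K matrices.
component_logdens <- function(model, X) {
  lapply(model$states, function(st) {
    K <- length(st$weights)
    out <- matrix(0, nrow(X), K)
    for (m in seq_len(K)) {
      mu <- st$means[m, ]
      v <- st$vars[m, ]
      xc <- sweep(X, 2L, mu, "-")
      out[, m] <- -0.5 * sum(log(2 * pi * v)) -
        rowSums(sweep(xc^2, 2L, 2 * v, "/"))
    }
    out
  })
}

# T x N matrix of state log-emission densities.
emission_logdens <- function(model, X, comp = NULL) {
  comp <- comp %||% component_logdens(model, X)
  N <- n_states(model)
  out <- matrix(0, nrow(X), N)
  for (j in seq_len(N)) {
    lw <- log(model$states[[j]]$weights)
    M <- sweep(comp[[j]], 2L, lw, "+")
    if (ncol(M) == 1L) {
      out[, j] <- M[, 1L]
    } else {
      mx <- apply(M, 1L, max)
      out[, j] <- mx + log(rowSums(exp(M - mx)))
    }
  }
  if (any(is.nan(out) | out == Inf)) {
    bad <- which(apply(is.nan(out) | out == Inf, 1L, any))
    stop("non-finite emission density at observation(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Log-space forward-backward recursions
#'
#' Computes the forward and backward lattices of an observation sequence in
#' log space, the sequence log-likelihood, and the per-step state
#' posteriors.
#'
#' @param model a [hmm_model()] or fitted [risk_hmm()].
#' @param obs T x D matrix or data.frame of observations (original units;
#'   the model's stored standardization is applied internally).
#' @return List of class `"hmm_trellis"`: `log_alpha`, `log_beta` (T x N),
#'   `gamma` (posteriors, rows sum to 1), `loglik`, and
#'   `loglik_backward` (the backward-recursion value of the same quantity).
#' @export
#' @examples
#' m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
#'                means = rbind(0, 3), vars = rbind(1, 1))
#' forward_backward(m, matrix(c(0.1, 2.9, 3.2)))$loglik
forward_backward <- function(model, obs) {
  X <- obs_matrix(model, obs)
  T_len <- nrow(X)
  if (T_len < 1L) stop("`obs` must be non-empty", call. = FALSE)
  N <- n_states(model)
  logB <- emission_logdens(model, X)
  logA <- log(model$A)
  log_alpha <- matrix(-Inf, T_len, N)
  log_alpha[1L, ] <- log(model$pi) + logB[1L, ]
  if (T_len > 1L) {
    for (t in 2L:T_len) {
      for (j in seq_len(N)) {
        log_alpha[t, j] <- logsumexp(log_alpha[t - 1L, ] + logA[, j]) + logB[t, j]
      }
    }
  }
  log_beta <- matrix(0, T_len, N)
  if (T_len > 1L) {
    for (t in (T_len - 1L):1L) {
      for (i in seq_len(N)) {
        log_beta[t, i] <- logsumexp(logA[i, ] + logB[t + 1L, ] + log_beta[t + 1L, ])
      }
    }
  }
  ll <- logsumexp(log_alpha[T_len, ])
  if (!is.finite(ll)) {
    stop("observation sequence has zero likelihood under the model",
         call. = FALSE)
  }
  ll_b <- logsumexp(log(model$pi) + logB[1L, ] + log_beta[1L, ])
  gamma <- exp(log_alpha + log_beta - ll)
  gamma <- gamma / rowSums(gamma)
  structure(list(log_alpha = log_alpha, log_beta = log_beta, gamma = gamma,
                 loglik = ll, loglik_backward = ll_b),
            class = "hmm_trellis")
}

#' Viterbi decoding
#'
#' Most probable joint hidden-state path; ties break toward the lower state
#' index at every step.
#'
#' @inheritParams forward_backward
#' @return Integer vector of state indices (1-based) of length T, with the
#'   decoded labels as the `"labels"` attribute.
#' @export
viterbi <- function(model, obs) {
  X <- obs_matrix(model, obs)
  T_len <- nrow(X)
  N <- n_states(model)
  logB <- emission_logdens(model, X)
  logA <- log(model$A)
  delta <- matrix(-Inf, T_len, N)
  psi <- matrix(1L, T_len, N)
  delta[1L, ] <- log(model$pi) + logB[1L, ]
  if (T_len > 1L) {
    for (t in 2L:T_len) {
      for (j in seq_len(N)) {
        cand <- delta[t - 1L, ] + logA[, j]
        psi[t, j] <- which.max(cand)    # first maximum = lower index on ties
        delta[t, j] <- cand[psi[t, j]] + logB[t, j]
      }
    }
  }
  path <- integer(T_len)
  path[T_len] <- which.max(delta[T_len, ])
  if (T_len > 1L) {
    for (t in (T_len - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  labels <- vapply(model$states, `[[`, "", "label")
  structure(path, labels = labels[path])
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi A = pi, sum(pi) = 1 for an irreducible, aperiodic stochastic
#' matrix. A (near-)identity or reducible matrix has no unique stationary
#' distribution and raises an error.
#'
#' @param A square row-stochastic matrix.
#' @param tol tolerance on eigenvalue multiplicity.
#' @return Probability vector.
#' @export
#' @examples
#' stationary_distribution(matrix(c(0.7529, 0.2471, 0.2537, 0.7463),
#'                                2, 2, byrow = TRUE))
stationary_distribution <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  if (!is_stochastic_matrix(A)) {
    stop("`A` must be row-stochastic", call. = FALSE)
  }
  e <- eigen(t(A))
  near_one <- abs(e$values - 1) < 1e-6
  if (sum(near_one) != 1L) {
    stop("stationary distribution is not unique (reducible or periodic chain)",
         call. = FALSE)
  }
  v <- Re(e$vectors[, which(near_one)])
  p <- v / sum(v)
  if (any(p < -tol)) stop("failed to find a valid stationary distribution")
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Label the states of a fitted model as safe / dangerous
#'
#' The state whose (mixture-averaged) SDNN emission mean is higher is
#' labelled safe: a larger SDNN indicates a more adaptable cardiac autonomic
#' state, characteristic of unstrained driving. States are reordered so that
#' state 1 is safe; an exact tie keeps the current order with a warning.
#'
#' @param model a `risk_hmm` whose features include an SDNN column
#'   (`"sdnn_ms"` or `"sdnn"`).
#' @return The model with states ordered (safe, dangerous) and labelled; the
#'   logical attribute-field `alignment_swapped` records whether a swap
#'   occurred.
#' @export
align_state_labels <- function(model) {
  k <- match_sdnn(model$feature_names)
  overall <- vapply(model$states, function(st) sum(st$weights * st$means[, k]), 1)
  if (overall[1L] == overall[2L]) {
    warning("SDNN emission means tie exactly; keeping state 1 as safe")
    ord <- c(1L, 2L)
  } else {
    ord <- order(overall, decreasing = TRUE)
  }
  out <- reorder_states(model, ord)
  out$alignment_swapped <- !identical(ord, c(1L, 2L))
  out
}

match_sdnn <- function(feature_names) {
  k <- which(feature_names %in% c("sdnn_ms", "sdnn"))
  if (!length(k)) {
    stop("model features do not include an SDNN column; cannot align labels",
         call. = FALSE)
  }
  k[1L]
}

reorder_states <- function(model, ord) {
  model$pi <- model$pi[ord]
  model$A <- model$A[ord, ord, drop = FALSE]
  model$states <- model$states[ord]
  for (j in seq_along(model$states)) {
    model$states[[j]]$label <- c("safe", "dangerous")[j]
  }
  model
}

#' Forecast the risk state
#'
#' Filters the observation prefix with the forward recursion and propagates
#' the filtered state posterior `horizon` steps ahead through the transition
#' matrix.
#'
#' @inheritParams forward_backward
#' @param horizon number of steps ahead (>= 0); 0 returns the filtered
#'   posterior of the last observation unchanged.
#' @return List of class `"risk_prediction"`: `filtered` (T x N posterior
#'   matrix), `path` (Viterbi decode of the prefix), `p_horizon` (state
#'   distribution at the horizon), `p_dangerous`, `horizon`, `labels`.
#' @export
predict_risk <- function(model, obs, horizon = 0L) {
  if (horizon < 0) stop("`horizon` must be >= 0", call. = FALSE)
  fb <- forward_backward(model, obs)
  T_len <- nrow(fb$log_alpha)
  la <- fb$log_alpha[T_len, ]
  filt_last <- exp(la - logsumexp(la))
  filtered <- exp(fb$log_alpha - apply(fb$log_alpha, 1L, logsumexp))
  p <- filt_last
  h <- as.integer(horizon)
  if (h > 0L) {
    Ah <- diag(n_states(model))
    M <- model$A
    # fast exponentiation; horizons are small but this keeps long ones exact
    while (h > 0L) {
      if (h %% 2L == 1L) Ah <- Ah %*% M
      M <- M %*% M
      h <- h %/% 2L
    }
    p <- as.numeric(filt_last %*% Ah)
  }
  labels <- vapply(model$states, `[[`, "", "label")
  names(p) <- labels
  structure(list(filtered = filtered, path = viterbi(model, obs),
                 p_horizon = p,
                 p_dangerous = unname(p[labels == "dangerous"][1L]),
                 horizon = as.integer(horizon), labels = labels),
            class = "risk_prediction")
}

#' Per-feature state contribution matrix
#'
#' Summarises how much each observed feature separates the two states: for
#' state j and feature k the contribution is the absolute safe-dangerous
#' mean difference weighted by state j's precision for that feature,
#' normalised so each row sums to 1. The output is a 2 x D row-stochastic
#' matrix analogous to the per-feature emission-share summaries reported
#' for field-trained models.
#'
#' @param model a fitted, label-aligned `risk_hmm`.
#' @return 2 x D matrix with rows (safe, dangerous) summing to 1.
#' @export
state_contributions <- function(model) {
  D <- length(model$feature_names)
  mu <- vapply(model$states, function(st) colSums(st$weights * st$means), numeric(D))
  # overall per-state variance: E[var] + var of component means
  v <- vapply(model$states, function(st) {
    m1 <- colSums(st$weights * st$means)
    colSums(st$weights * (st$vars + st$means^2)) - m1^2
  }, numeric(D))
  gap <- abs(mu[, 1L] - mu[, 2L])
  out <- t(vapply(seq_len(n_states(model)), function(j) {
    w <- gap / pmax(v[, j], .Machine$double.eps)
    if (sum(w) == 0) rep(1 / D, D) else w / sum(w)
  }, numeric(D)))
  dimnames(out) <- list(vapply(model$states, `[[`, "", "label"),
                        model$feature_names)
  out
}
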