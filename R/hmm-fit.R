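# Baum-Welch estimation of the two-state risk HMM.

# Vectorised two-argument logsumexp (elementwise over equal-length vectors).
vlse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Coerce the user's data argument into a list of T x D observation matrices.
as_sequence_list <- function(data, feature_names = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    seqs <- lapply(data, function(s) as.matrix(s))
    fn <- feature_names %||% colnames(seqs[[1L]]) %||%
      paste0("f", seq_len(ncol(seqs[[1L]])))
    seqs <- lapply(seqs, function(s) {
      colnames(s) <- fn
      s
    })
    return(list(sequences = seqs, feature_names = fn))
  }
  if (!is.data.frame(data)) stop("`data` must be a data.frame or a list of matrices")
  fn <- feature_names %||% intersect(FEATURES, names(data))
  if (!length(fn)) stop("no feature columns found in `data`", call. = FALSE)
  if ("complete" %in% names(data)) data <- data[data$complete == 1L, , drop = FALSE]
  grp <- if ("driver" %in% names(data)) data$driver else rep("s1", nrow(data))
  seqs <- lapply(split(data, grp), function(g) {
    as.matrix(g[, fn, drop = FALSE])
  })
  list(sequences = unname(seqs), feature_names = fn)
}

#' Fit a two-state driving-risk hidden Markov model
#'
#' Maximum-likelihood estimation by Baum-Welch (EM) of a two-state HMM with
#' Gaussian-mixture emissions over the four selected lane-change indicators
#' (or any supplied feature set). Features are z-scored with statistics of
#' the training data; the initial distribution and transition matrix start
#' at the uniform averaging values, emission means at a seeded 2-means split
#' of the pooled observations. After convergence the states are relabelled
#' so that state 1 ("safe") is the state with the higher SDNN emission mean,
#' when an SDNN feature is present.
#'
#' @param data a data.frame of observation rows (feature columns, optional
#'   `driver` grouping into sequences, optional `complete` flag), or a list
#'   of T x D matrices, each an observation sequence.
#' @param feature_names feature columns to use; defaults to the four
#'   selected indicators when present.
#' @param K mixture components per state (default 1).
#' @param structure `"ergodic"` (default) or `"left_right"`; the left-right
#'   topology forbids the return transition and keeps its zero pattern
#'   through every EM update.
#' @param standardize z-score features with training statistics (default
#'   TRUE).
#' @param tol relative log-likelihood gain below which EM stops.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed for the emission initialisation.
#' @param align relabel states by SDNN after fitting (default TRUE when an
#'   SDNN feature is present).
#' @param init optional `risk_hmm` supplying starting values for `pi`, `A`
#'   and the emission parameters (interpreted on the same scale as the data
#'   after any standardization), replacing the k-means initialisation.
#' @return A fitted object of class `"risk_hmm"`; see [hmm_model()] for the
#'   parameter slots. `$training` records the log-likelihood trace,
#'   iteration count, convergence flag and seed.
#' @seealso [forward_backward()], [viterbi()], [predict_risk()],
#'   [state_contributions()]
#' @export
#' @examples
#' truth <- hmm_model(c(0.5, 0.5), matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
#'                    means = rbind(c(0, 0), c(3, 3)), vars = rbind(c(1, 1), c(1, 1)))
#' seqs <- simulate(truth, nsim = 20, n_steps = 15, seed = 1)
#' fit <- risk_hmm(seqs$sequences, align = FALSE, seed = 2)
#' fit
risk_hmm <- function(data, feature_names = NULL, K = 1L,
                     structure = c("ergodic", "left_right"),
                     standardize = TRUE, tol = 1e-6, max_iter = 500L,
                     seed = 1L, align = NULL, init = NULL) {
  structure_kind <- match.arg(structure)
  sl <- as_sequence_list(data, feature_names)
  seqs <- sl$sequences
  fn <- sl$feature_names
  if (length(seqs) < 2L) {
    stop("at least two observation sequences are required", call. = FALSE)
  }
  K <- as.integer(K)
  N <- 2L
  D <- length(fn)
  X <- do.call(rbind, seqs)
  if (any(!is.finite(X))) stop("observations contain non-finite values", call. = FALSE)
  lens <- vapply(seqs, nrow, 1L)
  offsets <- cumsum(c(0L, lens[-length(lens)]))

  std <- NULL
  if (standardize) {
    mu0 <- colMeans(X)
    sd0 <- apply(X, 2L, stats::sd)
    sd0[sd0 == 0 | !is.finite(sd0)] <- 1
    std <- list(means = as.numeric(mu0), sds = as.numeric(sd0))
    X <- sweep(sweep(X, 2L, mu0, "-"), 2L, sd0, "/")
  }
  var_floor <- 1e-6 * pmax(apply(X, 2L, stats::var), .Machine$double.eps)

  if (is.null(init)) {
    em0 <- init_emissions(X, N, K, seed)
    pi <- rep(1 / N, N)
    A <- if (structure_kind == "left_right") {
      rbind(c(0.5, 0.5), c(0, 1))
    } else {
      matrix(1 / N, N, N)
    }
    weights <- em0$weights
    means <- em0$means
    vars <- lapply(em0$vars, function(v) pmax(v, var_floor))
  } else {
    if (!inherits(init, "risk_hmm")) stop("`init` must be a risk_hmm")
    pi <- init$pi
    A <- init$A
    weights <- lapply(init$states, `[[`, "weights")
    means <- lapply(init$states, `[[`, "means")
    vars <- lapply(init$states, function(s) pmax(s$vars, var_floor))
    if (length(weights[[1L]]) != K) K <- length(weights[[1L]])
  }
  mask <- A > 0

  trace <- numeric(0)
  respawned <- matrix(FALSE, N, K)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    model <- hmm_model(pi, A, means, vars, weights, feature_names = fn,
                       structure = structure_kind)
    comp <- component_logdens(model, X)
    logB <- emission_logdens(model, X, comp)
    es <- em_expectation(pi, A, logB, lens, offsets)
    ll <- es$loglik
    trace <- c(trace, ll)
    if (iter >= 2L) {
      gain <- ll - trace[iter - 1L]
      if (gain <= tol * abs(trace[iter - 1L])) {
        converged <- gain >= -1e-8 * abs(trace[iter - 1L])
        break
      }
    }
    if (iter >= max_iter) break

    # M-step
    pi <- es$pi_acc / length(seqs)
    pi <- pi / sum(pi)
    A_new <- es$xi_acc
    A_new[!mask] <- 0
    rs <- rowSums(A_new)
    for (i in seq_len(N)) {
      A_new[i, ] <- if (rs[i] > 0) A_new[i, ] / rs[i] else A[i, ]
    }
    if (structure_kind == "left_right") A_new[N, ] <- c(rep(0, N - 1L), 1)
    A <- A_new

    G <- es$gamma
    occ <- colSums(G)
    if (any(occ < 1e-8)) {
      stop("a hidden state lost all occupancy during EM", call. = FALSE)
    }
    for (j in seq_len(N)) {
      lw <- log(weights[[j]])
      EPS <- G[, j] * exp(sweep(comp[[j]], 2L, lw, "+") - logB[, j])
      wsum <- colSums(EPS)
      for (m in seq_len(K)) {
        if (wsum[m] < 1e-10) {
          # component collapse: re-spawn once at a random data row
          if (respawned[j, m]) {
            stop("mixture component (state ", j, ", component ", m,
                 ") collapsed twice", call. = FALSE)
          }
          respawned[j, m] <- TRUE
          ridx <- 1L + (child_seed(seed, iter * N * K + j * K + m) %% nrow(X))
          means[[j]][m, ] <- X[ridx, ]
          vars[[j]][m, ] <- pmax(apply(X, 2L, stats::var), var_floor)
          weights[[j]][m] <- 1e-3
          weights[[j]] <- weights[[j]] / sum(weights[[j]])
          next
        }
        mu_new <- colSums(EPS[, m] * X) / wsum[m]
        xc <- sweep(X, 2L, mu_new, "-")
        v_new <- colSums(EPS[, m] * xc^2) / wsum[m]
        means[[j]][m, ] <- mu_new
        vars[[j]][m, ] <- pmax(v_new, var_floor)
      }
      if (sum(wsum) > 0) {
        w_new <- wsum / sum(wsum)
        if (all(w_new > 0)) weights[[j]] <- w_new
      }
    }
  }

  model <- hmm_model(pi, A, means, vars, weights, feature_names = fn,
                     structure = structure_kind, standardization = std)
  model$training <- list(loglik = trace[length(trace)], loglik_trace = trace,
                         iterations = iter, converged = converged,
                         seed = as.integer(seed), n_sequences = length(seqs),
                         n_obs = nrow(X))
  model$call <- match.call()
  do_align <- align %||% any(fn %in% c("sdnn_ms", "sdnn"))
  if (do_align) model <- align_state_labels(model)
  model
}

# Seeded k-means initialisation of the emission parameters.
init_emissions <- function(X, N, K, seed) {
  D <- ncol(X)
  km <- with_seed(child_seed(seed, 1L), {
    if (nrow(unique(X)) <= N) {
      list(cluster = rep_len(seq_len(N), nrow(X)))
    } else {
      stats::kmeans(X, centers = N, nstart = 5L, iter.max = 50L)
    }
  })
  means <- vector("list", N)
  vars <- vector("list", N)
  weights <- vector("list", N)
  for (j in seq_len(N)) {
    rows <- X[km$cluster == j, , drop = FALSE]
    if (!nrow(rows)) rows <- X
    if (K == 1L || nrow(unique(rows)) <= K) {
      mu <- matrix(colMeans(rows), 1L, D)
      v <- matrix(apply(rows, 2L, stats::var), 1L, D)
      v[!is.finite(v) | v == 0] <- 1
      means[[j]] <- mu[rep(1L, K), , drop = FALSE] +
        if (K > 1L) 0.1 * matrix(with_seed(child_seed(seed, j + 10L),
                                           stats::rnorm(K * D)), K, D) else 0
      vars[[j]] <- v[rep(1L, K), , drop = FALSE]
    } else {
      km2 <- with_seed(child_seed(seed, j + 100L),
                       stats::kmeans(rows, centers = K, nstart = 3L,
                                     iter.max = 50L))
      means[[j]] <- km2$centers
      vars[[j]] <- t(vapply(seq_len(K), function(m) {
        r <- rows[km2$cluster == m, , drop = FALSE]
        v <- if (nrow(r) >= 2L) apply(r, 2L, stats::var) else rep(1, D)
        v[!is.finite(v) | v == 0] <- 1
        v
      }, numeric(D)))
    }
    weights[[j]] <- rep(1 / K, K)
  }
  list(means = means, vars = vars, weights = weights)
}

# E-step over all sequences, vectorised across sequences of equal length.
# Returns total loglik, summed initial-state posteriors, summed transition
# counts, and the stacked per-observation state posteriors.
em_expectation <- function(pi, A, logB, lens, offsets) {
  N <- length(pi)
  logA <- log(A)
  lpi <- log(pi)
  n_obs <- nrow(logB)
  G <- matrix(0, n_obs, N)
  pi_acc <- numeric(N)
  xi_acc <- matrix(0, N, N)
  loglik <- 0

  for (T_len in unique(lens)) {
    sel <- which(lens == T_len)
    idx <- outer(offsets[sel], seq_len(T_len), "+")  # n_g x T
    n_g <- length(sel)
    LA <- array(-Inf, c(n_g, T_len, N))
    for (j in seq_len(N)) LA[, 1L, j] <- lpi[j] + logB[idx[, 1L], j]
    if (T_len > 1L) {
      for (t in 2L:T_len) {
        for (j in seq_len(N)) {
          acc <- LA[, t - 1L, 1L] + logA[1L, j]
          for (i in seq_len(N)[-1L]) {
            acc <- vlse2(acc, LA[, t - 1L, i] + logA[i, j])
          }
          LA[, t, j] <- acc + logB[idx[, t], j]
        }
      }
    }
    ll_seq <- LA[, T_len, 1L]
    for (j in seq_len(N)[-1L]) ll_seq <- vlse2(ll_seq, LA[, T_len, j])
    loglik <- loglik + sum(ll_seq)

    LBt <- array(0, c(n_g, T_len, N))
    if (T_len > 1L) {
      for (t in (T_len - 1L):1L) {
        for (i in seq_len(N)) {
          acc <- logA[i, 1L] + logB[idx[, t + 1L], 1L] + LBt[, t + 1L, 1L]
          for (j in seq_len(N)[-1L]) {
            acc <- vlse2(acc, logA[i, j] + logB[idx[, t + 1L], j] + LBt[, t + 1L, j])
          }
          LBt[, t, i] <- acc
        }
      }
    }
    for (t in seq_len(T_len)) {
      gm <- exp(matrix(LA[, t, ], n_g, N) + matrix(LBt[, t, ], n_g, N) - ll_seq)
      gm <- gm / rowSums(gm)
      G[idx[, t], ] <- gm
      if (t == 1L) pi_acc <- pi_acc + colSums(gm)
    }
    if (T_len > 1L) {
      for (t in seq_len(T_len - 1L)) {
        for (i in seq_len(N)) {
          for (j in seq_len(N)) {
            if (!is.finite(logA[i, j])) next
            xi_acc[i, j] <- xi_acc[i, j] +
              sum(exp(LA[, t, i] + logA[i, j] + logB[idx[, t + 1L], j] +
                        LBt[, t + 1L, j] - ll_seq))
          }
        }
      }
    }
  }
  list(loglik = loglik, pi_acc = pi_acc, xi_acc = xi_acc, gamma = G)
}
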