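# Shared fixtures: small models and exhaustive-enumeration oracles.

published_A <- matrix(c(0.7529, 0.2471, 0.2537, 0.7463), 2L, 2L, byrow = TRUE)
published_pi <- c(0.8584, 0.1416)

feature_names4 <- c("fixation_duration_ms", "saccade_range_deg",
                    "sdnn_ms", "avg_speed_kmh")

# A random single-component 2-state model with D-dimensional emissions.
random_model <- function(seed, D = 2L) {
  set.seed(seed)
  a <- runif(2L, 0.05, 0.95)
  A <- rbind(c(a[1L], 1 - a[1L]), c(1 - a[2L], a[2L]))
  p <- runif(1L, 0.05, 0.95)
  hmm_model(pi = c(p, 1 - p), A = A,
            means = matrix(rnorm(2L * D, sd = 2), 2L, D),
            vars = matrix(runif(2L * D, 0.3, 2), 2L, D))
}

# Single-component state emission density at one observation.
state_dens <- function(model, x, j) {
  st <- model$states[[j]]
  prod(stats::dnorm(x, st$means[1L, ], sqrt(st$vars[1L, ])))
}

# Exhaustive path-sum log-likelihood (oracle for forward_backward).
brute_loglik <- function(model, obs) {
  T_len <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_len)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- model$pi[s[1L]] * state_dens(model, obs[1L, ], s[1L])
    if (T_len > 1L) for (t in 2L:T_len) {
      p <- p * model$A[s[t - 1L], s[t]] * state_dens(model, obs[t, ], s[t])
    }
    total <- total + p
  }
  log(total)
}

# Exhaustive argmax path (oracle for viterbi); lexicographically first
# maximiser, which matches lower-index tie-breaking.
brute_viterbi <- function(model, obs) {
  T_len <- nrow(obs)
  grid <- expand.grid(rep(list(1:2), T_len))
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  paths <- as.matrix(grid)
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(model$pi[s[1L]]) + log(state_dens(model, obs[1L, ], s[1L]))
    if (T_len > 1L) for (t in 2L:T_len) {
      lp <- lp + log(model$A[s[t - 1L], s[t]]) +
        log(state_dens(model, obs[t, ], s[t]))
    }
    if (lp > best) {
      best <- lp
      best_path <- s
    }
  }
  unname(best_path)
}

# Well-separated 4-feature truth model used in recovery experiments
# (safe state carries the higher SDNN mean).
recovery_truth <- function() {
  hmm_model(pi = c(0.5, 0.5),
            A = matrix(c(0.75, 0.25, 0.25, 0.75), 2L, byrow = TRUE),
            means = rbind(c(0, 0, 0, 0), c(3, 3, -3, 3)),
            vars = rbind(rep(1, 4L), rep(1, 4L)),
            feature_names = feature_names4)
}
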