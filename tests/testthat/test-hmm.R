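# HMM recursions, decoding, training and chain utilities.

test_that("model construction enforces the normalization invariants", {
  expect_error(hmm_model(c(0.6, 0.5), matrix(0.5, 2, 2),
                         means = rbind(0, 1), vars = rbind(1, 1)),
               "probability vector")
  expect_error(hmm_model(c(0.5, 0.5), matrix(c(0.9, 0.3, 0.2, 0.8), 2),
                         means = rbind(0, 1), vars = rbind(1, 1)),
               "row-stochastic")
  expect_error(hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
                         means = rbind(0, 1), vars = rbind(0, 1)),
               "positive")
  # left-right topology: no return transition, absorbing last state
  expect_error(hmm_model(c(0.5, 0.5), matrix(c(0.7, 0.3, 0.2, 0.8), 2,
                                             byrow = TRUE),
                         means = rbind(0, 1), vars = rbind(1, 1),
                         structure = "left_right"),
               "left_right")
  lr <- hmm_model(c(0.5, 0.5), rbind(c(0.7, 0.3), c(0, 1)),
                  means = rbind(0, 1), vars = rbind(1, 1),
                  structure = "left_right")
  expect_s3_class(lr, "risk_hmm")
})

test_that("the forward recursion base case matches the direct mixture sum", {
  m <- random_model(1, D = 2L)
  x <- matrix(c(0.3, -0.4), 1L)
  direct <- log(m$pi[1L] * state_dens(m, x[1L, ], 1L) +
                  m$pi[2L] * state_dens(m, x[1L, ], 2L))
  expect_equal(forward_backward(m, x)$loglik, direct, tolerance = 1e-12)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(3)
  m <- random_model(3, D = 2L)
  obs <- matrix(rnorm(6), 3L, 2L)
  fb <- forward_backward(m, obs)
  expect_equal(fb$loglik, brute_loglik(m, obs), tolerance = 1e-10)
  expect_equal(fb$loglik, fb$loglik_backward, tolerance = 1e-8)
  expect_equal(rowSums(fb$gamma), rep(1, 3L), tolerance = 1e-9)
})

test_that("forward and backward log-likelihoods agree on 50 random models", {
  for (s in 1:50) {
    m <- random_model(s, D = 2L)
    set.seed(s + 1000L)
    obs <- matrix(rnorm(2L * sample(2:12, 1L)), ncol = 2L)
    fb <- forward_backward(m, obs)
    expect_equal(fb$loglik, fb$loglik_backward, tolerance = 1e-8)
    expect_equal(rowSums(fb$gamma), rep(1, nrow(obs)), tolerance = 1e-9)
  }
})

test_that("Viterbi equals the exhaustive argmax and honours the prior", {
  # identical emissions: the sticky prior pins the path to state 1
  same <- hmm_model(c(1, 0), matrix(c(0.9, 0.1, 0.1, 0.9), 2L, byrow = TRUE),
                    means = rbind(c(0, 0), c(0, 0)), vars = rbind(c(1, 1), c(1, 1)))
  set.seed(5)
  obs <- matrix(rnorm(10), 5L, 2L)
  expect_identical(as.integer(viterbi(same, obs)), rep(1L, 5L))

  for (s in 1:100) {
    m <- random_model(s + 500L, D = 2L)
    set.seed(s)
    T_len <- sample(2:10, 1L)
    obs <- matrix(rnorm(2L * T_len), T_len, 2L)
    expect_identical(as.integer(viterbi(m, obs)), brute_viterbi(m, obs))
  }
})

test_that("decoding recovers strongly separated synthetic states", {
  truth <- hmm_model(c(0.5, 0.5), matrix(c(0.8, 0.2, 0.2, 0.8), 2L, byrow = TRUE),
                     means = rbind(c(0, 0), c(4, 4)), vars = rbind(c(1, 1), c(1, 1)))
  sim <- simulate(truth, nsim = 50L, n_steps = 40L, seed = 9)
  hits <- 0L; total <- 0L
  for (i in seq_along(sim$sequences)) {
    path <- as.integer(viterbi(truth, sim$sequences[[i]]))
    hits <- hits + sum(path == sim$states[[i]])
    total <- total + length(path)
  }
  expect_gte(hits / total, 0.99)
})

test_that("EM increases the likelihood monotonically on seeded fits", {
  for (s in 1:5) {
    truth <- random_model(s + 2000L, D = 2L)
    sim <- simulate(truth, nsim = 30L, n_steps = 12L, seed = s)
    fit <- risk_hmm(sim$sequences, seed = s, align = FALSE, max_iter = 100L)
    tr <- fit$training$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("Baum-Welch recovers the generating parameters", {
  truth <- recovery_truth()
  sim <- simulate(truth, nsim = 1000L, n_steps = 20L, seed = 7)
  fit <- risk_hmm(sim$sequences, seed = 7)
  # alignment: state 1 = safe = higher SDNN mean = generator state 1
  expect_identical(fit$states[[1L]]$label, "safe")
  expect_lt(max(abs(fit$A - truth$A)), 0.05)
  mu_nat <- do.call(rbind, coef(fit, scale = "natural")$means)
  mu_true <- do.call(rbind, lapply(truth$states, `[[`, "means"))
  expect_lt(max(abs(mu_nat - mu_true)), 0.1)
})

test_that("single-state data keeps the symmetric EM fixed point at the pooled mean", {
  # all observations come from one state (A = identity, pi = (1, 0)); with
  # the averaging initial values and indistinguishable states, EM's fixed
  # point puts every state mean at the pooled sample mean
  one_state <- hmm_model(c(1, 0), diag(2), means = rbind(c(0, 0), c(50, 50)),
                         vars = rbind(c(1, 1), c(1, 1)))
  sim <- simulate(one_state, nsim = 20L, n_steps = 10L, seed = 11)
  X <- do.call(rbind, sim$sequences)
  pooled <- colMeans(X)
  symmetric <- hmm_model(c(0.5, 0.5), matrix(0.5, 2L, 2L),
                         means = rbind(c(0, 0), c(0, 0)),
                         vars = rbind(c(1, 1), c(1, 1)))
  fit <- risk_hmm(sim$sequences, seed = 1, align = FALSE,
                  standardize = FALSE, max_iter = 50L, init = symmetric)
  mu <- do.call(rbind, lapply(fit$states, function(s) s$means[1L, ]))
  expect_lt(max(abs(sweep(mu, 2L, pooled, "-"))), 1e-6)
})

test_that("the left-right zero pattern survives training", {
  truth <- hmm_model(c(1, 0), rbind(c(0.9, 0.1), c(0, 1)),
                     means = rbind(c(0, 0), c(3, 3)), vars = rbind(c(1, 1), c(1, 1)),
                     structure = "left_right")
  sim <- simulate(truth, nsim = 40L, n_steps = 15L, seed = 13)
  fit <- risk_hmm(sim$sequences, structure = "left_right", seed = 13,
                  align = FALSE)
  expect_identical(fit$A[2L, 1L], 0)
  expect_identical(fit$A[2L, 2L], 1)
  expect_true(all(diff(fit$training$loglik_trace) >=
                    -1e-8 * abs(fit$training$loglik_trace[-1L])))
})

test_that("stationary distributions solve the balance equations", {
  expect_equal(stationary_distribution(matrix(0.5, 2L, 2L)), c(0.5, 0.5))
  p <- stationary_distribution(published_A)
  expect_equal(p, c(0.5066, 0.4934), tolerance = 1e-4)
  expect_equal(as.numeric(p %*% published_A), p, tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "not unique")
})

test_that("risk forecasts propagate the filtered posterior through A", {
  sharp <- hmm_model(c(1, 0), published_A,
                     means = rbind(c(10, 10, 10, 10), c(-10, -10, -10, -10)),
                     vars = rbind(rep(1, 4L), rep(1, 4L)),
                     feature_names = feature_names4)
  obs <- matrix(c(10, 10, 10, 10), 1L)
  p0 <- predict_risk(sharp, obs, horizon = 0L)
  expect_equal(unname(p0$p_horizon), c(1, 0), tolerance = 1e-12)
  p1 <- predict_risk(sharp, obs, horizon = 1L)
  expect_equal(p1$p_dangerous, 0.2471, tolerance = 1e-9)
  p_inf <- predict_risk(sharp, obs, horizon = 200L)
  expect_equal(unname(p_inf$p_horizon),
               as.numeric(stationary_distribution(published_A)),
               tolerance = 1e-6)
})

test_that("state labelling follows the SDNN mean with a tie warning", {
  m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2L, 2L),
                 means = rbind(c(0, 0, -1, 0), c(0, 0, 1, 0)),
                 vars = matrix(1, 2L, 4L), feature_names = feature_names4)
  aligned <- align_state_labels(m)
  expect_identical(aligned$states[[1L]]$label, "safe")
  expect_equal(aligned$states[[1L]]$means[1L, 3L], 1)
  expect_true(aligned$alignment_swapped)

  tie <- hmm_model(c(0.5, 0.5), matrix(0.5, 2L, 2L),
                   means = rbind(c(0, 0, 1, 0), c(5, 5, 1, 5)),
                   vars = matrix(1, 2L, 4L), feature_names = feature_names4)
  expect_warning(out <- align_state_labels(tie), "tie")
  expect_identical(out$states[[1L]]$label, "safe")
  expect_false(out$alignment_swapped)
})

test_that("state contributions are row-stochastic and rank separating features", {
  m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2L, 2L),
                 means = rbind(c(0, 0, 2, 0), c(0, 0, -2, 0)),
                 vars = matrix(1, 2L, 4L), feature_names = feature_names4)
  cm <- state_contributions(m)
  expect_equal(rowSums(cm), c(safe = 1, dangerous = 1), tolerance = 1e-9)
  expect_identical(colnames(cm)[which.max(cm["safe", ])], "sdnn_ms")
})
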