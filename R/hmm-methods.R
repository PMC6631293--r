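# S3 methods for fitted risk_hmm objects.

state_labels <- function(model) vapply(model$states, `[[`, "", "label")

#' @export
print.risk_hmm <- function(x, digits = 4L, ...) {
  cat("Two-state driving-risk hidden Markov model",
      if (x$structure == "left_right") "(left-right)" else "(ergodic)", "\n")
  labs <- state_labels(x)
  cat("States:", paste(labs, collapse = ", "),
      " Features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("\nInitial distribution:\n")
  print(round(stats::setNames(x$pi, labs), digits))
  cat("\nTransition matrix:\n")
  A <- x$A
  dimnames(A) <- list(labs, labs)
  print(round(A, digits))
  if (!is.null(x$training)) {
    cat("\nlog-likelihood:", format(x$training$loglik, digits = 8L),
        " EM iterations:", x$training$iterations,
        if (x$training$converged) "(converged)" else "(not converged)", "\n")
  }
  invisible(x)
}

#' @export
summary.risk_hmm <- function(object, ...) {
  nat <- coef(object, scale = "natural")
  mu <- t(vapply(seq_along(nat$means),
                 function(j) colSums(nat$weights[[j]] * nat$means[[j]]),
                 numeric(length(object$feature_names))))
  dimnames(mu) <- list(state_labels(object), object$feature_names)
  out <- list(model = object, emission_means = mu,
              contributions = state_contributions(object),
              stationary = tryCatch(stationary_distribution(object$A),
                                    error = function(e) NULL))
  class(out) <- "summary.risk_hmm"
  out
}

#' @export
print.summary.risk_hmm <- function(x, digits = 4L, ...) {
  print(x$model, digits = digits)
  cat("\nEmission means (natural units, mixture-averaged):\n")
  print(round(x$emission_means, digits))
  cat("\nPer-feature state contributions (rows sum to 1):\n")
  print(round(x$contributions, digits))
  if (!is.null(x$stationary)) {
    cat("\nStationary distribution:\n")
    print(round(stats::setNames(x$stationary, state_labels(x$model)), digits))
  }
  invisible(x)
}

#' Extract fitted HMM parameters
#'
#' @param object a `risk_hmm`.
#' @param scale `"standardized"` returns the parameters on the internal
#'   z-scored feature scale; `"natural"` maps means and variances back to
#'   the original units.
#' @param ... unused.
#' @return List with `pi`, `A`, `weights` (list), `weights_mat` (N x K),
#'   `means` and `vars` (lists of K x D matrices), `feature_names`.
#' @export
coef.risk_hmm <- function(object, scale = c("standardized", "natural"), ...) {
  scale <- match.arg(scale)
  means <- lapply(object$states, `[[`, "means")
  vars <- lapply(object$states, `[[`, "vars")
  std <- object$standardization
  if (scale == "natural" && !is.null(std)) {
    means <- lapply(means, function(m) sweep(sweep(m, 2L, std$sds, "*"),
                                             2L, std$means, "+"))
    vars <- lapply(vars, function(v) sweep(v, 2L, std$sds^2, "*"))
  }
  w <- lapply(object$states, `[[`, "weights")
  list(pi = object$pi, A = object$A, weights = w,
       weights_mat = do.call(rbind, w), means = means, vars = vars,
       feature_names = object$feature_names)
}

#' @export
logLik.risk_hmm <- function(object, ...) {
  if (is.null(object$training)) {
    stop("model was not fitted; no stored log-likelihood", call. = FALSE)
  }
  N <- length(object$pi)
  K <- length(object$states[[1L]]$weights)
  D <- length(object$feature_names)
  free_A <- if (object$structure == "left_right") N - 1L else N * (N - 1L)
  df <- (N - 1L) + free_A + N * (K - 1L) + N * K * D * 2L
  structure(object$training$loglik, df = df, nobs = object$training$n_obs,
            class = "logLik")
}

#' Predict hidden risk states for new observations
#'
#' @param object a fitted `risk_hmm`.
#' @param newdata a T x D matrix/data.frame (one sequence) or a list of
#'   them.
#' @param type `"states"` for the Viterbi path, `"posterior"` for smoothed
#'   per-step state posteriors, `"risk"` for a forward-filtered forecast
#'   (see [predict_risk()]).
#' @param horizon forecast horizon for `type = "risk"`.
#' @param ... unused.
#' @return For one sequence: a character vector of state labels, a T x N
#'   posterior matrix, or a `risk_prediction`. For a list, a list of these.
#' @export
predict.risk_hmm <- function(object, newdata,
                             type = c("states", "posterior", "risk"),
                             horizon = 0L, ...) {
  type <- match.arg(type)
  one <- function(obs) {
    switch(type,
           states = attr(viterbi(object, obs), "labels"),
           posterior = {
             g <- forward_backward(object, obs)$gamma
             colnames(g) <- state_labels(object)
             g
           },
           risk = predict_risk(object, obs, horizon = horizon))
  }
  if (is.list(newdata) && !is.data.frame(newdata)) {
    lapply(newdata, one)
  } else {
    one(newdata)
  }
}

#' Simulate observation sequences from a risk HMM
#'
#' Draws hidden state paths from the model's Markov chain and observations
#' from the corresponding Gaussian-mixture emissions, mapped back to
#' natural units when the model carries standardization statistics.
#'
#' @param object a `risk_hmm`.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param n_steps length of each sequence.
#' @param ... unused.
#' @return List with `sequences` (list of T x D matrices) and `states`
#'   (list of integer state-index vectors, 1 = first state).
#' @export
simulate.risk_hmm <- function(object, nsim = 1L, seed = 1L, n_steps = 10L, ...) {
  N <- length(object$pi)
  D <- length(object$feature_names)
  std <- object$standardization
  with_seed(seed, {
    seqs <- vector("list", nsim)
    paths <- vector("list", nsim)
    for (s in seq_len(nsim)) {
      st <- integer(n_steps)
      st[1L] <- sample.int(N, 1L, prob = object$pi)
      if (n_steps > 1L) for (t in 2L:n_steps) {
        st[t] <- sample.int(N, 1L, prob = object$A[st[t - 1L], ])
      }
      X <- matrix(0, n_steps, D)
      for (t in seq_len(n_steps)) {
        state <- object$states[[st[t]]]
        m <- sample.int(length(state$weights), 1L, prob = state$weights)
        X[t, ] <- stats::rnorm(D, state$means[m, ], sqrt(state$vars[m, ]))
      }
      if (!is.null(std)) {
        X <- sweep(sweep(X, 2L, std$sds, "*"), 2L, std$means, "+")
      }
      colnames(X) <- object$feature_names
      seqs[[s]] <- X
      paths[[s]] <- st
    }
    list(sequences = seqs, states = paths)
  })
}

#' Posterior-mean residuals of a fitted risk HMM
#'
#' For each observation and feature, the deviation from the
#' posterior-weighted emission mean scaled by the posterior-weighted
#' emission SD (on the standardized feature scale). Useful as a rough
#' goodness-of-fit screen; values far beyond +/- 3 indicate observations
#' that no state explains well.
#'
#' @param object a fitted `risk_hmm`.
#' @param newdata observation sequence (matrix or data.frame); defaults to
#'   nothing and must be supplied.
#' @param ... unused.
#' @return T x D matrix of scaled residuals.
#' @export
residuals.risk_hmm <- function(object, newdata, ...) {
  X <- obs_matrix(object, newdata)
  g <- forward_backward(object, newdata)$gamma
  D <- length(object$feature_names)
  mu <- vapply(object$states, function(st) colSums(st$weights * st$means),
               numeric(D))
  v <- vapply(object$states, function(st) {
    m1 <- colSums(st$weights * st$means)
    colSums(st$weights * (st$vars + st$means^2)) - m1^2
  }, numeric(D))
  Ehat <- g %*% t(mu)
  Vhat <- g %*% t(pmax(v, .Machine$double.eps))
  out <- (X - Ehat) / sqrt(Vhat)
  colnames(out) <- object$feature_names
  out
}

#' @export
plot.risk_hmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  if (!is.null(x$training)) {
    graphics::plot(x$training$loglik_trace, type = "b", pch = 20,
                   xlab = "EM iteration", ylab = "log-likelihood",
                   main = "Baum-Welch trace")
  }
  cm <- state_contributions(x)
  graphics::barplot(cm, beside = TRUE, legend.text = rownames(cm),
                    las = 2L, ylab = "contribution share",
                    main = "Feature contributions")
  invisible(x)
}

#' @export
print.risk_prediction <- function(x, digits = 4L, ...) {
  cat("Risk forecast at horizon", x$horizon, "\n")
  cat("P(state) =", paste(sprintf("%s %.4f", names(x$p_horizon), x$p_horizon),
                          collapse = ", "), "\n")
  cat("P(dangerous) =", round(x$p_dangerous, digits), "\n")
  invisible(x)
}
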