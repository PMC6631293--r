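# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Canonical stage ordering of the lane-changing process.
STAGES <- c("car_following", "perception", "intention", "execution")
LOS_LEVELS <- c("I", "II", "III", "IV")
DURATION_BINS <- c("lt40", "40_80", "80_120", "gt120")
FEATURES <- c("fixation_duration_ms", "saccade_range_deg", "sdnn_ms", "avg_speed_kmh")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and an index (kept < 2^31).
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# log(sum(exp(x))) without overflow; handles -Inf blocks.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_stochastic_matrix <- function(A, tol = 1e-8) {
  is.matrix(A) && nrow(A) == ncol(A) && all(is.finite(A)) && all(A >= -tol) &&
    all(abs(rowSums(A) - 1) <= tol)
}

stopifnot_prob_vector <- function(p, name = "pi", tol = 1e-8) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must be a probability vector summing to 1", name), call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
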