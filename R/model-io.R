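# Versioned JSON serialization of risk_hmm models.

HMM_SCHEMA_VERSION <- "1.0"

#' Write / read a risk HMM as versioned JSON
#'
#' The on-disk schema stores `schema_version`, `structure`, `pi`, `A`, one
#' record per state (`label`, `weights`, `means`, `covariances` as diagonal
#' variance rows), `feature_names`, the standardization statistics and the
#' training metadata. Round-tripping preserves parameters to full double
#' precision.
#'
#' @param model a `risk_hmm`.
#' @param path JSON file path.
#' @return `write_hmm_json()` returns `path` invisibly; `read_hmm_json()`
#'   returns a `risk_hmm`.
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(
    schema_version = HMM_SCHEMA_VERSION,
    structure = model$structure,
    pi = model$pi,
    A = model$A,
    states = lapply(model$states, function(st) {
      list(label = st$label, weights = st$weights, means = st$means,
           covariances = st$vars)
    }),
    feature_names = model$feature_names,
    standardization = model$standardization,
    training = if (!is.null(model$training)) {
      list(loglik_trace = model$training$loglik_trace,
           iterations = model$training$iterations,
           seed = model$training$seed)
    }
  )
  # I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- obj$schema_version %||% NA_character_
  if (!identical(as.character(ver), HMM_SCHEMA_VERSION)) {
    stop("unsupported model schema_version: ", ver,
         " (this build reads ", HMM_SCHEMA_VERSION, ")", call. = FALSE)
  }
  A <- obj$A
  if (!is.matrix(A)) A <- do.call(rbind, lapply(obj$A, unlist))
  has_emissions <- !is.null(obj$states) &&
    (is.data.frame(obj$states) || length(obj$states) > 0L)
  if (!has_emissions) {
    # summary-only parameter set (e.g. the published fixture): carry the
    # chain parameters and any printed contribution matrix, no densities.
    out <- list(pi = as.numeric(obj$pi), A = A,
                states = NULL, feature_names = obj$feature_names,
                structure = obj$structure %||% "ergodic",
                standardization = NULL, training = NULL,
                printed_contribution_matrix =
                  if (!is.null(obj$printed_contribution_matrix)) {
                    m <- obj$printed_contribution_matrix
                    if (!is.matrix(m)) m <- do.call(rbind, m)
                    m
                  })
    class(out) <- c("risk_hmm_summary", "risk_hmm")
    return(out)
  }
  states <- obj$states
  if (is.data.frame(states)) {
    states <- lapply(seq_len(nrow(states)), function(i) as.list(states[i, ]))
  }
  to_mat <- function(x) {
    if (is.matrix(x)) x else if (is.list(x)) do.call(rbind, x) else matrix(x, nrow = 1L)
  }
  labels <- vapply(states, function(s) as.character(s$label), "")
  means <- lapply(states, function(s) to_mat(s$means))
  vars <- lapply(states, function(s) to_mat(s$covariances))
  weights <- lapply(states, function(s) as.numeric(unlist(s$weights)))
  std <- obj$standardization
  if (!is.null(std)) std <- list(means = as.numeric(std$means),
                                 sds = as.numeric(std$sds))
  model <- hmm_model(pi = as.numeric(obj$pi), A = A, means = means,
                     vars = vars, weights = weights,
                     feature_names = as.character(obj$feature_names),
                     structure = obj$structure %||% "ergodic",
                     standardization = std, labels = labels)
  if (!is.null(obj$training)) {
    model$training <- list(loglik = utils::tail(obj$training$loglik_trace, 1L),
                           loglik_trace = as.numeric(obj$training$loglik_trace),
                           iterations = obj$training$iterations,
                           converged = NA,
                           seed = obj$training$seed,
                           n_sequences = NA_integer_,
                           n_obs = NA_integer_)
  }
  model
}

#' Published reference model parameters
#'
#' Loads the packaged parameter set reported from a 500-event field study
#' of the lane-changing process (25 drivers): the initial safe/dangerous
#' distribution, the 2 x 2 state transition matrix, and the printed 2 x 4
#' per-feature contribution shares over (fixation duration, saccade range,
#' SDNN, average speed). The contribution matrix is a printed summary, not
#' a Gaussian-mixture emission parameterisation, so the object carries no
#' emission densities and supports only chain-level operations such as
#' [stationary_distribution()].
#'
#' @return A `risk_hmm_summary` object with elements `pi`, `A`,
#'   `printed_contribution_matrix`, `feature_names`.
#' @export
#' @examples
#' m <- published_model()
#' stationary_distribution(m$A)
published_model <- function() {
  path <- system.file("extdata", "published_model.json", package = "riskhmm",
                      mustWork = TRUE)
  read_hmm_json(path)
}
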