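#' CTHMM-GLM model parameters
#'
#' Bundles the full parameter block of a K-state continuous-time hidden
#' Markov model with a generalized-linear observation layer: the initial
#' distribution \code{pi}, the infinitesimal generator \code{Q}, the D x K
#' coefficient matrix \code{B} (row 1 is the intercept, column k the
#' state-k linear predictor) and the observation family.
#'
#' @param pi initial distribution over the K states.
#' @param Q K x K generator matrix.
#' @param B D x K coefficient matrix (a vector is treated as 1 x K).
#' @param family \code{"normal"} (identity link, dispersion \code{sigma}) or
#'   \code{"poisson"} (log link).
#' @param sigma residual standard deviation, normal family only.
#' @return An object of class \code{cthmm_model}.
#' @examples
#' m <- cthmm_model(pi = c(.5, .5),
#'                  Q = generator_matrix(matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)),
#'                  B = c(-1, 1), family = "normal", sigma = 1)
#' @export
cthmm_model <- function(pi, Q, B, family = c("normal", "poisson"), sigma = NULL) {
  family <- match.arg(family)
  if (is.vector(B)) B <- matrix(B, nrow = 1)
  m <- structure(list(K = length(pi), pi = as.numeric(pi), Q = as.matrix(Q),
                      B = as.matrix(B), family = family,
                      sigma = if (family == "normal") as.numeric(sigma) else NULL),
                 class = "cthmm_model")
  validate_cthmm_model(m)
  m
}

#' @rdname cthmm_model
#' @param model object to validate.
#' @export
validate_cthmm_model <- function(model) {
  stopifnot(inherits(model, "cthmm_model"))
  K <- model$K
  if (length(model$pi) != K || any(model$pi < 0) || abs(sum(model$pi) - 1) > 1e-8)
    stop("pi must be a length-K probability vector")
  validate_generator(model$Q)
  if (nrow(model$Q) != K) stop("Q must be K x K")
  if (ncol(model$B) != K || !all(is.finite(model$B)))
    stop("B must be a finite D x K matrix")
  if (model$family == "normal" &&
      (length(model$sigma) != 1L || !is.finite(model$sigma) || model$sigma <= 0))
    stop("normal family needs a single dispersion sigma > 0")
  invisible(model)
}

#' @export
print.cthmm_model <- function(x, ...) {
  cat(sprintf("<cthmm_model: K = %d states, %s family, D = %d covariate(s)>\n",
              x$K, x$family, nrow(x$B)))
  invisible(x)
}

#' GLM observation log-density
#'
#' Log-density of one outcome given its covariate vector and a state's
#' coefficient column: Gaussian with identity link or Poisson with log link.
#'
#' @param o outcome value.
#' @param z covariate vector (first entry 1).
#' @param beta_k coefficient column for the occupied state.
#' @param family \code{"normal"} or \code{"poisson"}.
#' @param sigma Gaussian residual standard deviation.
#' @return Log-density.
#' @export
glm_logdensity <- function(o, z, beta_k, family = c("normal", "poisson"),
                           sigma = NULL) {
  family <- match.arg(family)
  if (length(z) != length(beta_k)) stop("covariate / coefficient length mismatch")
  eta <- sum(z * beta_k)
  if (family == "normal") {
    dnorm(o, mean = eta, sd = sigma, log = TRUE)
  } else {
    if (any(o < 0) || any(o != round(o)))
      stop("poisson outcomes must be non-negative integers")
    dpois(o, lambda = exp(min(eta, 700)), log = TRUE)
  }
}

# stacked emission log-density matrix (total observations x K)
emission_logf <- function(model, data) {
  eta <- data$Z %*% model$B
  K <- model$K
  if (model$family == "normal") {
    lf <- dnorm(rep(data$outcome, K), mean = as.vector(eta),
                sd = model$sigma, log = TRUE)
  } else {
    if (any(data$outcome < 0) || any(data$outcome != round(data$outcome)))
      stop("poisson outcomes must be non-negative integers")
    lf <- dpois(rep(data$outcome, K), lambda = exp(pmin(as.vector(eta), 700)),
                log = TRUE)
  }
  matrix(lf, ncol = K)
}

# forward marginal log-likelihood; returns per-subject vector or the total;
# -Inf signals zero likelihood (used for MH rejection), never NaN
.forward_loglik <- function(model, data, per_subject = FALSE) {
  if (data$n_subjects == 0L) return(if (per_subject) numeric(0) else 0)
  ll <- cpp_forward_loglik(model$pi, model$Q, emission_logf(model, data),
                           data$time, data$offsets)
  if (per_subject) as.vector(ll) else sum(ll)
}

#' Forward (marginal) log-likelihood of a CTHMM
#'
#' Integrates the latent continuous-time path out of the likelihood via the
#' forward recursion over the discrete observation skeleton, using interval
#' transition matrices \eqn{\exp(Q \Delta t)} and per-step scaling so that
#' long series (e.g. 60 observations) do not underflow.
#'
#' @param model a [cthmm_model()].
#' @param data a [as_cthmm_data()] dataset.
#' @param per_subject return the per-subject vector instead of the total.
#' @return Total (or per-subject) log-likelihood.
#' @export
forward_marginal_loglik <- function(model, data, per_subject = FALSE) {
  validate_cthmm_model(model)
  stopifnot(inherits(data, "cthmm_data"))
  if (nrow(model$B) != ncol(data$Z)) stop("model and data disagree on D")
  ll <- .forward_loglik(model, data, per_subject = TRUE)
  bad <- which(!is.finite(ll))
  if (length(bad))
    stop(sprintf("non-finite forward likelihood for subject %d", bad[1]))
  if (per_subject) ll else sum(ll)
}

#' Complete-data log-likelihood of a CTHMM
#'
#' Joint log-density of the observations and the full latent trajectories:
#' initial-state terms, exponential dwell terms \eqn{q_{xx}\,t}, jump terms
#' \eqn{\log q_{x x'}}, and the GLM observation terms at the states occupied
#' at the observation times.
#'
#' @inheritParams forward_marginal_loglik
#' @param paths list of [latent_path()] objects, one per subject, each
#'   covering that subject's observation window.
#' @return Log-likelihood value.
#' @export
complete_data_loglik <- function(model, paths, data) {
  validate_cthmm_model(model)
  stopifnot(inherits(data, "cthmm_data"), length(paths) == data$n_subjects)
  lf <- emission_logf(model, data)
  total <- 0
  for (n in seq_len(data$n_subjects)) {
    idx <- (data$offsets[n] + 1L):data$offsets[n + 1L]
    tt <- data$time[idx]
    p <- paths[[n]]
    validate_latent_path(p)
    if (max(p$states) > model$K) stop("path states exceed K")
    if (p$horizon < tt[length(tt)] - 1e-9)
      stop(sprintf("path for subject %d does not cover its observation window", n))
    total <- total + log(model$pi[p$states[1]])
    ns <- length(p$states)
    ends <- c(p$times[-1], p$horizon)
    total <- total + sum(diag(model$Q)[p$states] * (ends - p$times))
    if (ns > 1L)
      total <- total + sum(log(model$Q[cbind(p$states[-ns], p$states[-1])]))
    st <- path_state_at(p, tt)
    total <- total + sum(lf[cbind(idx, st)])
  }
  total
}
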