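#' Impute latent continuous-time paths given parameters
#'
#' Draws the latent trajectories from their exact conditional law given the
#' data and the current parameters: forward-filtering backward-sampling of
#' the discrete skeleton at the observation times, then endpoint-conditioned
#' path sampling inside every inter-observation interval.  Also returns the
#' CTMC sufficient statistics of the imputed paths.
#'
#' @param model a [cthmm_model()].
#' @param data a [as_cthmm_data()] dataset.
#' @param keep_paths also return the full paths as [latent_path()] objects.
#' @param max_attempts rejection-sampling attempts per interval before the
#'   uniformization fallback.
#' @return List with \code{skeleton} (stacked 1-based states at observation
#'   times), \code{ntrans} (K x K jump counts), \code{dwell} (time per
#'   state), \code{init_counts}, and optionally \code{paths}.
#' @export
impute_paths <- function(model, data, keep_paths = FALSE, max_attempts = 30L) {
  validate_cthmm_model(model)
  stopifnot(inherits(data, "cthmm_data"))
  K <- model$K
  if (data$n_subjects == 0L) {
    return(list(skeleton = integer(0), ntrans = matrix(0, K, K),
                dwell = rep(0, K), init_counts = rep(0L, K),
                paths = if (keep_paths) list() else NULL))
  }
  lf <- emission_logf(model, data)
  r <- cpp_impute_paths(model$pi, model$Q, lf, data$time, data$offsets,
                        keep_paths, as.integer(max_attempts))
  out <- list(skeleton = as.integer(r$skeleton), ntrans = r$ntrans,
              dwell = as.vector(r$dwell), init_counts = as.integer(r$init_counts))
  if (keep_paths) {
    out$paths <- lapply(seq_len(data$n_subjects), function(n) {
      p <- r$paths[[n]]
      horizon <- data$time[data$offsets[n + 1L]]
      # single-observation subjects have a zero-length window
      latent_path(p$states + 1L, p$times, max(horizon, 0))
    })
  }
  out
}

#' Conjugate update of the generator Q
#'
#' Given imputed-path sufficient statistics, each off-diagonal rate has the
#' Gamma full conditional \eqn{q_{ij} \sim Gamma(a + N_{ij}, b + T_i)}.
#'
#' @param stats list with \code{ntrans} and \code{dwell} as returned by
#'   [impute_paths()].
#' @param prior a [prior_spec()].
#' @param K number of states (defaults to the dimension of \code{ntrans}).
#' @return A new generator matrix.
#' @export
update_Q <- function(stats, prior, K = nrow(stats$ntrans)) {
  if (K == 1L) return(matrix(0, 1, 1))
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    Q[i, j] <- rgamma(1, shape = prior$q_shape + stats$ntrans[i, j],
                      rate = prior$q_rate + stats$dwell[i])
  generator_matrix(Q)
}

#' Conjugate update of the initial distribution
#'
#' Dirichlet full conditional with the initial-state counts added to the
#' concentration.
#'
#' @param init_counts length-K vector of initial-state counts.
#' @param prior a [prior_spec()].
#' @return A probability vector.
#' @export
update_pi <- function(init_counts, prior) {
  rdirichlet1(prior$pi_conc + init_counts)
}

#' Update the GLM coefficients (and Gaussian dispersion)
#'
#' Normal-identity family: per-state conjugate multivariate-normal draw of
#' the coefficient column given \eqn{\sigma}, then an inverse-gamma draw of
#' \eqn{\sigma^2} (unless fixed).  The normal coefficient prior acts as a
#' ridge, so states with fewer observations than covariates still have a
#' proper full conditional.  Poisson-log family: per-column random-walk
#' Metropolis on \eqn{\beta_k}; states with no assigned observations are
#' redrawn from the prior.
#'
#' @param model current [cthmm_model()].
#' @param skeleton stacked 1-based latent states at the observation times.
#' @param data the dataset.
#' @param prior a [prior_spec()].
#' @param scales per-state random-walk standard deviations (Poisson only).
#' @param fix_sigma if non-NULL, hold sigma at this value.
#' @return List with \code{B}, \code{sigma}, \code{scales} and per-state
#'   Metropolis \code{accept} indicators.
#' @export
update_B <- function(model, skeleton, data, prior, scales = NULL,
                     fix_sigma = NULL) {
  K <- model$K
  D <- nrow(model$B)
  B <- model$B
  accept <- rep(NA, K)
  if (is.null(scales)) scales <- rep(0.3, K)
  if (model$family == "normal") {
    sigma <- if (is.null(fix_sigma)) model$sigma else fix_sigma
    if (prior$beta_prior != "normal")
      stop("normal family requires the normal coefficient prior")
    prec0 <- diag(1 / prior$beta_sd^2, D)
    m0 <- rep(prior$beta_mean, D)
    for (k in seq_len(K)) {
      idx <- which(skeleton == k)
      if (length(idx) == 0L) {
        B[, k] <- rnorm(D, prior$beta_mean, prior$beta_sd)
        next
      }
      Zk <- data$Z[idx, , drop = FALSE]
      ok <- data$outcome[idx]
      A <- crossprod(Zk) / sigma^2 + prec0
      bb <- crossprod(Zk, ok) / sigma^2 + prec0 %*% m0
      R <- chol(A)
      mean_k <- backsolve(R, backsolve(R, bb, transpose = TRUE))
      B[, k] <- mean_k + backsolve(R, rnorm(D))
    }
    if (is.null(fix_sigma)) {
      resid <- data$outcome - rowSums(data$Z * t(B[, skeleton, drop = FALSE]))
      sigma <- sqrt(1 / rgamma(1,
        shape = prior$sigma_shape + length(resid) / 2,
        rate = prior$sigma_rate + sum(resid^2) / 2))
    }
    return(list(B = B, sigma = sigma, scales = scales, accept = accept))
  }
  # poisson-log family: per-column random-walk MH
  for (k in seq_len(K)) {
    idx <- which(skeleton == k)
    if (length(idx) == 0L) {
      B[, k] <- draw_prior_B(D, 1L, prior)
      next
    }
    Zk <- data$Z[idx, , drop = FALSE]
    ok <- data$outcome[idx]
    logpost <- function(bk) {
      eta <- pmin(as.vector(Zk %*% bk), 700)
      sum(dpois(ok, exp(eta), log = TRUE)) +
        log_prior_B(matrix(bk, ncol = 1), prior)
    }
    cur <- B[, k]
    cand <- cur + rnorm(D) * scales[k]
    lr <- logpost(cand) - logpost(cur)
    accept[k] <- is.finite(lr) && log(runif(1)) < lr
    if (accept[k]) B[, k] <- cand
  }
  list(B = B, sigma = model$sigma, scales = scales, accept = accept)
}

# One fixed-K sweep in the printed order: latent paths, B (and sigma), pi, Q.
# `ctrl` carries the adaptive Poisson scales and the adaptation step index.
sweep_fixed_k <- function(model, data, prior, ctrl = list()) {
  scales <- ctrl$scales
  if (is.null(scales)) scales <- rep(0.3, model$K)
  imp <- impute_paths(model, data)
  up <- update_B(model, imp$skeleton, data, prior, scales = scales,
                 fix_sigma = ctrl$fix_sigma)
  B <- up$B
  sigma <- up$sigma
  scales <- up$scales
  if (model$family == "poisson" && isTRUE(ctrl$adapt)) {
    it <- max(ctrl$iter, 1)
    acc <- up$accept
    adj <- exp((ifelse(is.na(acc), 0, ifelse(acc, 1, 0)) - 0.35) / sqrt(it))
    scales <- pmin(pmax(scales * adj, 1e-3), 10)
  }
  pi <- update_pi(imp$init_counts, prior)
  Q <- update_Q(imp, prior, K = model$K)
  model2 <- cthmm_model(pi, Q, B, model$family, sigma)
  list(model = model2, imp = imp, scales = scales, accept = up$accept)
}
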