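#' Prior specification for CTHMM samplers
#'
#' Collects all hyperparameters: independent Gamma(\code{q_shape},
#' \code{q_rate}) priors on the off-diagonal generator rates, a symmetric
#' Dirichlet(\code{pi_conc}) prior on the initial distribution, a prior on
#' the GLM coefficients, an inverse-gamma prior on the Gaussian variance,
#' and mass functions on the number of hidden states K and of mixture
#' components M.
#'
#' The coefficient prior is either \code{"normal"} (independent
#' N(\code{beta_mean}, \code{beta_sd}^2) on every entry of B; the default
#' \code{beta_sd = 100} is a proper noninformative choice) or
#' \code{"poisson-rate"}, which for intercept-only Poisson models places
#' Gamma(\code{rate_shape}, \code{rate_rate}) on each state mean
#' \eqn{e^{\beta_{1,k}}} (the prior on the intercept follows by change of
#' variables).
#'
#' @param q_shape,q_rate Gamma prior on each off-diagonal \eqn{q_{ij}}.
#' @param pi_conc Dirichlet concentration for \eqn{\pi}.
#' @param beta_prior \code{"normal"} or \code{"poisson-rate"}.
#' @param beta_mean,beta_sd normal coefficient prior parameters.
#' @param rate_shape,rate_rate Gamma prior on Poisson state means
#'   (intercept-only models).
#' @param sigma_shape,sigma_rate inverse-gamma prior on \eqn{\sigma^2}.
#' @param k_prior prior on the number of states, from [count_prior()].
#' @param Kmax hard cap on the number of states.
#' @param m_prior prior on the number of mixture components.
#' @param Mmax hard cap on the number of components.
#' @param delta_mix Dirichlet concentration on the mixture weights.
#' @return An object of class \code{cthmm_prior}.
#' @export
prior_spec <- function(q_shape = 1, q_rate = 2, pi_conc = 1,
                       beta_prior = c("normal", "poisson-rate"),
                       beta_mean = 0, beta_sd = 100,
                       rate_shape = 10, rate_rate = 10,
                       sigma_shape = 0.01, sigma_rate = 0.01,
                       k_prior = count_prior("ztpois", lambda = 3.5),
                       Kmax = 10L,
                       m_prior = count_prior("ztpois", lambda = 3.5),
                       Mmax = 15L, delta_mix = 1) {
  beta_prior <- match.arg(beta_prior)
  stopifnot(q_shape > 0, q_rate > 0, pi_conc > 0, beta_sd > 0,
            rate_shape > 0, rate_rate > 0, sigma_shape > 0, sigma_rate > 0,
            Kmax >= 1, Mmax >= 1, delta_mix > 0)
  structure(list(q_shape = q_shape, q_rate = q_rate, pi_conc = pi_conc,
                 beta_prior = beta_prior, beta_mean = beta_mean,
                 beta_sd = beta_sd, rate_shape = rate_shape,
                 rate_rate = rate_rate, sigma_shape = sigma_shape,
                 sigma_rate = sigma_rate, k_prior = k_prior,
                 Kmax = as.integer(Kmax), m_prior = m_prior,
                 Mmax = as.integer(Mmax), delta_mix = delta_mix),
            class = "cthmm_prior")
}

#' Priors on a count of states or components
#'
#' Mass functions on \{1, 2, ...\}, truncated and renormalized over
#' \code{1..cap} when evaluated: zero-truncated Poisson, geometric (support
#' shifted to start at 1), zero-truncated negative binomial, and discrete
#' uniform.
#'
#' @param type one of \code{"ztpois"}, \code{"geometric"}, \code{"ztnbinom"},
#'   \code{"uniform"}.
#' @param lambda Poisson mean (before truncation).
#' @param p success probability (geometric / negative binomial).
#' @param r negative binomial size.
#' @return An object of class \code{count_prior}.
#' @export
count_prior <- function(type = c("ztpois", "geometric", "ztnbinom", "uniform"),
                        lambda = 3.5, p = 0.2, r = 2) {
  type <- match.arg(type)
  structure(list(type = type, lambda = lambda, p = p, r = r),
            class = "count_prior")
}

# normalized log pmf over 1..cap
count_prior_logpmf <- function(kp, cap) {
  k <- seq_len(cap)
  lp <- switch(kp$type,
    ztpois = dpois(k, kp$lambda, log = TRUE),
    geometric = stats::dgeom(k - 1L, kp$p, log = TRUE),
    ztnbinom = stats::dnbinom(k, size = kp$r, prob = kp$p, log = TRUE),
    uniform = rep(0, cap))
  lp - logsumexp(lp)
}

log_p0_count <- function(k, kp, cap) {
  if (k < 1 || k > cap) return(-Inf)
  count_prior_logpmf(kp, cap)[k]
}

# log prior density of a full parameter block Theta_K = (pi, Q, B[, sigma])
log_prior_theta <- function(model, prior, include_sigma = FALSE) {
  K <- model$K
  lp <- 0
  if (K > 1L) {
    off <- model$Q[row(model$Q) != col(model$Q)]
    lp <- lp + sum(dgamma(off, shape = prior$q_shape, rate = prior$q_rate,
                          log = TRUE))
  }
  lp <- lp + ldirichlet(model$pi, rep(prior$pi_conc, K))
  lp <- lp + log_prior_B(model$B, prior)
  if (include_sigma && model$family == "normal") {
    s2 <- model$sigma^2
    lp <- lp + prior$sigma_shape * log(prior$sigma_rate) -
      lgamma(prior$sigma_shape) - (prior$sigma_shape + 1) * log(s2) -
      prior$sigma_rate / s2
  }
  lp
}

log_prior_B <- function(B, prior) {
  if (prior$beta_prior == "normal") {
    sum(dnorm(B, prior$beta_mean, prior$beta_sd, log = TRUE))
  } else {
    if (nrow(B) != 1L)
      stop("the poisson-rate coefficient prior requires an intercept-only model")
    sum(dgamma(exp(B), shape = prior$rate_shape, rate = prior$rate_rate,
               log = TRUE) + B)
  }
}

# prior draw of Theta_K
draw_prior_theta <- function(K, D, family, prior, sigma = NULL) {
  Q <- matrix(0, K, K)
  if (K > 1L) {
    off <- rgamma(K * (K - 1L), shape = prior$q_shape, rate = prior$q_rate)
    Q[row(Q) != col(Q)] <- off
    Q <- generator_matrix(Q)
  }
  pi <- rdirichlet1(rep(prior$pi_conc, K))
  B <- draw_prior_B(D, K, prior)
  if (family == "normal" && is.null(sigma))
    sigma <- sqrt(1 / rgamma(1, shape = prior$sigma_shape, rate = prior$sigma_rate))
  cthmm_model(pi, Q, B, family, sigma)
}

draw_prior_B <- function(D, K, prior) {
  if (prior$beta_prior == "normal") {
    matrix(rnorm(D * K, prior$beta_mean, prior$beta_sd), D, K)
  } else {
    matrix(log(rgamma(K, shape = prior$rate_shape, rate = prior$rate_rate)),
           1, K)
  }
}
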