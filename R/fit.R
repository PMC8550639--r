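# data-driven starting point at K = 1; all other structure is learned
.init_model <- function(data, K, family, prior, fix_sigma = NULL) {
  D <- ncol(data$Z)
  if (data$n_subjects == 0L)
    return(draw_prior_theta(K, D, family, prior, sigma = fix_sigma))
  m <- mean(data$outcome)
  B <- matrix(0, D, K)
  if (family == "normal") {
    B[1, ] <- m + (seq_len(K) - (K + 1) / 2) * sd(data$outcome) / max(K - 1, 1)
    sigma <- if (is.null(fix_sigma)) max(sd(data$outcome), 1e-3) else fix_sigma
  } else {
    B[1, ] <- log(pmax(m, 0.1)) + (seq_len(K) - (K + 1) / 2) * 0.2
    sigma <- NULL
  }
  Q <- if (K > 1L) generator_matrix(matrix(0.5, K, K)) else matrix(0, 1, 1)
  cthmm_model(rep(1 / K, K), Q, B, family, sigma)
}

.resize_scales <- function(scales, K) {
  if (length(scales) == K) return(scales)
  rep(exp(mean(log(scales))), K)
}

#' Posterior sampling with a fixed number of states
#'
#' Runs the fixed-dimension Gibbs/Metropolis sweep: latent-path imputation,
#' coefficient (and dispersion) update, initial-distribution update and
#' generator update, in that order.
#'
#' @param data a [as_cthmm_data()] dataset.
#' @param K number of hidden states.
#' @param family \code{"normal"} or \code{"poisson"}.
#' @param prior a [prior_spec()].
#' @param iterations total MCMC sweeps.
#' @param burnin sweeps discarded by the summary functions.
#' @param fix_sigma optionally hold the Gaussian dispersion fixed.
#' @param verbose print progress every 1000 sweeps.
#' @return An object of class \code{cthmm_fixed_fit} with per-iteration
#'   draws of B, sigma, pi and Q.
#' @export
fit_cthmm_fixed <- function(data, K, family = c("normal", "poisson"),
                            prior = prior_spec(), iterations = 2000L,
                            burnin = min(500L, iterations %/% 4L),
                            fix_sigma = NULL, verbose = FALSE) {
  family <- match.arg(family)
  model <- .init_model(data, K, family, prior, fix_sigma)
  D <- nrow(model$B)
  draws <- list(B = array(NA_real_, c(iterations, D, K)),
                sigma = rep(NA_real_, iterations),
                pi = matrix(NA_real_, iterations, K),
                Q = array(NA_real_, c(iterations, K, K)),
                loglik = rep(NA_real_, iterations))
  scales <- rep(0.3, K)
  for (it in seq_len(iterations)) {
    sw <- sweep_fixed_k(model, data, prior,
                        ctrl = list(scales = scales, adapt = TRUE, iter = it,
                                    fix_sigma = fix_sigma))
    model <- sw$model
    scales <- sw$scales
    draws$B[it, , ] <- model$B
    draws$sigma[it] <- if (family == "normal") model$sigma else NA_real_
    draws$pi[it, ] <- model$pi
    draws$Q[it, , ] <- model$Q
    if (verbose && it %% 1000L == 0L)
      message(sprintf("sweep %d / %d", it, iterations))
  }
  structure(list(draws = draws, K = K, family = family, prior = prior,
                 iterations = iterations, burnin = burnin,
                 fix_sigma = fix_sigma, final_model = model),
            class = "cthmm_fixed_fit")
}

#' Summarize a fixed-K fit
#'
#' Posterior means and equal-tailed 95% credible intervals for the
#' coefficient matrix, dispersion, initial distribution and generator,
#' after burn-in.
#'
#' @param object a \code{cthmm_fixed_fit}.
#' @param ... unused.
#' @return A list of summary tables.
#' @export
summary.cthmm_fixed_fit <- function(object, ...) {
  keep <- seq(object$burnin + 1L, object$iterations)
  qfun <- function(x) c(mean = mean(x), lo = unname(quantile(x, 0.025)),
                        hi = unname(quantile(x, 0.975)))
  B <- apply(object$draws$B[keep, , , drop = FALSE], c(2, 3), mean)
  B_ci <- apply(object$draws$B[keep, , , drop = FALSE], c(2, 3), qfun)
  out <- list(B_mean = B, B_ci = B_ci,
              pi_mean = colMeans(object$draws$pi[keep, , drop = FALSE]),
              Q_mean = apply(object$draws$Q[keep, , , drop = FALSE], c(2, 3), mean))
  if (object$family == "normal")
    out$sigma <- qfun(object$draws$sigma[keep])
  out
}

#' Reversible-jump sampling of the number of hidden states
#'
#' Alternates one trans-dimensional split/combine step on K (accepted jumps
#' refresh the latent paths implicitly, since every fixed-K sweep begins by
#' re-imputing them under the current parameters) with one fixed-K sweep.
#' The chain starts from a one-state model.
#'
#' @inheritParams fit_cthmm_fixed
#' @param cfg a [move_config()].
#' @param keep_models store the per-iteration parameter snapshots.
#' @return An object of class \code{cthmm_rj_fit} with a per-iteration
#'   trace (K, move, accepted, log acceptance, forward log-likelihood).
#' @export
fit_cthmm_rj <- function(data, family = c("normal", "poisson"),
                         prior = prior_spec(), cfg = move_config(),
                         iterations = 5000L,
                         burnin = min(1000L, iterations %/% 4L),
                         fix_sigma = NULL, keep_models = TRUE,
                         verbose = FALSE) {
  family <- match.arg(family)
  model <- .init_model(data, 1L, family, prior, fix_sigma)
  trace <- data.frame(iter = seq_len(iterations), K = NA_integer_,
                      move = NA_character_, accepted = NA,
                      log_alpha = NA_real_, loglik = NA_real_)
  models <- if (keep_models) vector("list", iterations) else NULL
  scales <- rep(0.3, 1L)
  ll <- NULL
  for (it in seq_len(iterations)) {
    rj <- rj_state_step(model, data, prior, cfg, ll_current = ll)
    model <- rj$model
    scales <- .resize_scales(scales, model$K)
    sw <- sweep_fixed_k(model, data, prior,
                        ctrl = list(scales = scales, adapt = TRUE, iter = it,
                                    fix_sigma = fix_sigma))
    model <- sw$model
    scales <- sw$scales
    ll <- NULL  # parameters changed; recompute next step
    trace$K[it] <- model$K
    trace$move[it] <- rj$move
    trace$accepted[it] <- rj$accepted
    trace$log_alpha[it] <- rj$log_alpha
    trace$loglik[it] <- rj$loglik
    if (keep_models) models[[it]] <- model
    if (verbose && it %% 500L == 0L)
      message(sprintf("iteration %d / %d (K = %d)", it, iterations, model$K))
  }
  structure(list(trace = trace, models = models, family = family,
                 prior = prior, cfg = cfg, iterations = iterations,
                 burnin = burnin),
            class = "cthmm_rj_fit")
}

#' Posterior distribution of the number of hidden states
#'
#' @param fit a \code{cthmm_rj_fit}.
#' @param burnin iterations to drop (defaults to the fit's burn-in).
#' @return Data frame with columns \code{K} and \code{prob}.
#' @export
k_posterior <- function(fit, burnin = fit$burnin) {
  k <- fit$trace$K[fit$trace$iter > burnin]
  tab <- table(factor(k, levels = seq_len(max(k))))
  data.frame(K = as.integer(names(tab)), prob = as.numeric(tab) / length(k))
}

#' @export
print.cthmm_rj_fit <- function(x, ...) {
  kp <- k_posterior(x)
  cat(sprintf("<cthmm_rj_fit: %d iterations, modal K = %d (mass %.3f)>\n",
              x$iterations, kp$K[which.max(kp$prob)], max(kp$prob)))
  invisible(x)
}

#' Parameter summary conditional on the modal number of states
#'
#' Pools the post burn-in iterations whose K equals the posterior mode and
#' reports the state intercepts sorted increasingly (a simple identifiable
#' functional under label switching), with posterior means and equal-tailed
#' 95% intervals.
#'
#' @param fit a \code{cthmm_rj_fit} run with \code{keep_models = TRUE}.
#' @param burnin iterations to drop.
#' @return List with the modal \code{K}, sorted-intercept summary matrix and
#'   the number of pooled iterations.
#' @export
modal_k_summary <- function(fit, burnin = fit$burnin) {
  if (is.null(fit$models)) stop("fit was run with keep_models = FALSE")
  kp <- k_posterior(fit, burnin)
  kmode <- kp$K[which.max(kp$prob)]
  sel <- which(fit$trace$iter > burnin & fit$trace$K == kmode)
  ints <- t(vapply(fit$models[sel], function(m) sort(m$B[1, ]),
                   numeric(kmode)))
  summ <- apply(ints, 2, function(x)
    c(mean = mean(x), sd = sd(x), lo = unname(quantile(x, 0.025)),
      hi = unname(quantile(x, 0.975))))
  list(K = kmode, intercepts = summ, n_iterations = length(sel))
}

#' Write a per-iteration trace as JSON lines
#'
#' One JSON object per iteration: iteration index, K, move type, accepted
#' flag, log acceptance and forward log-likelihood (plus M, weights and
#' per-component state counts for clustering fits).
#'
#' @param fit a \code{cthmm_rj_fit} or \code{cthmm_cluster_fit}.
#' @param path output file.
#' @export
write_trace_jsonl <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tr <- fit$trace
  cluster <- !is.null(fit$Ks)
  for (i in seq_len(nrow(tr))) {
    row <- as.list(tr[i, , drop = FALSE])
    if (cluster) {
      row$K <- I(fit$Ks[[i]])
      row$weights <- I(fit$weights[[i]])
    }
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                na = "null"),
               con)
  }
  invisible(path)
}
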