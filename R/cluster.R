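#' Finite mixture of CTHMMs
#'
#' M mixture components, each a full [cthmm_model()] with its own number of
#' hidden states, plus mixture weights on the simplex.
#'
#' @param weights length-M probability vector.
#' @param components list of [cthmm_model()] objects.
#' @return An object of class \code{cthmm_mixture}.
#' @export
mixture_model <- function(weights, components) {
  m <- structure(list(M = length(weights), weights = as.numeric(weights),
                      components = components),
                 class = "cthmm_mixture")
  validate_mixture_model(m)
  m
}

#' @rdname mixture_model
#' @param model object to validate.
#' @export
validate_mixture_model <- function(model) {
  stopifnot(inherits(model, "cthmm_mixture"))
  if (model$M < 1L || length(model$components) != model$M)
    stop("weights/components length mismatch")
  if (any(model$weights < 0) || abs(sum(model$weights) - 1) > 1e-8)
    stop("mixture weights must lie on the simplex")
  for (cm in model$components) validate_cthmm_model(cm)
  invisible(model)
}

#' @export
print.cthmm_mixture <- function(x, ...) {
  cat(sprintf("<cthmm_mixture: M = %d components, states (%s)>\n", x$M,
              paste(vapply(x$components, `[[`, 0L, "K"), collapse = ", ")))
  invisible(x)
}

# N x M matrix of per-subject forward log-likelihoods under each component
component_logliks <- function(model, data) {
  ll <- vapply(model$components, function(cm) .forward_loglik(cm, data, TRUE),
               numeric(data$n_subjects))
  matrix(ll, nrow = data$n_subjects, ncol = model$M)
}

#' Posterior membership probabilities
#'
#' For each subject, the probability of each mixture component given the
#' data, with the latent paths marginalized out: component m gets weight
#' \eqn{\varpi_m} times the component's forward marginal likelihood,
#' normalized in log space.
#'
#' @param model a [mixture_model()].
#' @param data a [as_cthmm_data()] dataset.
#' @param ll optional precomputed N x M matrix of per-subject component
#'   log-likelihoods.
#' @return N x M matrix of probabilities (rows sum to 1).
#' @export
membership_posterior <- function(model, data, ll = NULL) {
  validate_mixture_model(model)
  if (is.null(ll)) ll <- component_logliks(model, data)
  lw <- sweep(ll, 2, log(model$weights), `+`)
  pw <- exp(sweep(lw, 1, apply(lw, 1, max), `-`))
  pw / rowSums(pw)
}

#' Marginal log-likelihood of a CTHMM mixture
#'
#' \eqn{\sum_n \log \sum_m \varpi_m L(o_n | \Theta^{(m)}, K_m)}, with both
#' the component labels and the latent paths integrated out.
#'
#' @inheritParams membership_posterior
#' @return Log-likelihood value.
#' @export
mixture_marginal_loglik <- function(model, data, ll = NULL) {
  validate_mixture_model(model)
  if (data$n_subjects == 0L) return(0)
  if (is.null(ll)) ll <- component_logliks(model, data)
  lw <- sweep(ll, 2, log(model$weights), `+`)
  sum(apply(lw, 1, logsumexp))
}

# split probability for component moves
b_of_m <- function(M, cfg) {
  if (cfg$Mmax <= 1L) 0 else if (M <= 1L) 1 else if (M >= cfg$Mmax) 0 else
    cfg$b_split_m
}

.comp_dist <- function(model, a, b) {
  sqrt(sum((model$components[[a]]$B - model$components[[b]]$B)^2))
}

# same-state-count candidates for a combine partner
.same_k_candidates <- function(model, m) {
  Ks <- vapply(model$components, `[[`, 0L, "K")
  setdiff(which(Ks == Ks[m]), m)
}

# ordered selections (first uniform, partner argmin L2 among same-K) that
# yield the unordered pair {m, mp}
.comp_pair_orderings <- function(model, m, mp) {
  n <- 0L
  for (o in list(c(m, mp), c(mp, m))) {
    cand <- .same_k_candidates(model, o[1])
    if (length(cand) == 0L) next
    d <- vapply(cand, function(j) .comp_dist(model, o[1], j), numeric(1))
    if (cand[which.min(d)] == o[2]) n <- n + 1L
  }
  n
}

# log prior of a full mixture configuration (weights, component sizes and
# parameter blocks, and the count M itself)
log_prior_mixture <- function(model, prior) {
  lp <- log_p0_count(model$M, prior$m_prior, prior$Mmax) +
    ldirichlet(model$weights, rep(prior$delta_mix, model$M))
  for (cm in model$components)
    lp <- lp + log_p0_count(cm$K, prior$k_prior, prior$Kmax) +
      log_prior_theta(cm, prior)
  lp
}

#' Centered split of a mixture component
#'
#' Duplicates component m (same Q and pi in both children), perturbs every
#' state intercept of the second child by N(0, c^2) noise, and divides the
#' mixture weight by a Beta(2,2) draw.  The new child is appended as
#' component M+1.
#'
#' @param model a [mixture_model()].
#' @param m component to split.
#' @param cfg a [move_config()].
#' @param prior a [prior_spec()].
#' @return List with the proposed \code{model},
#'   \code{log_proposal_ratio} and adjacency flag \code{admissible}.
#' @export
propose_component_split <- function(model, m, cfg, prior) {
  M <- model$M
  if (M >= cfg$Mmax) stop("component split unavailable at Mmax")
  comp <- model$components[[m]]
  K <- comp$K
  bnew <- rnorm(K, comp$B[1, ], cfg$c)
  child <- comp
  child$B[1, ] <- bnew
  w <- rbeta(1, 2, 2)
  weights <- c(model$weights, (1 - w) * model$weights[m])
  weights[m] <- w * model$weights[m]
  comps <- c(model$components, list(child))
  new_model <- mixture_model(weights, comps)
  admissible <- TRUE
  cand <- .same_k_candidates(new_model, m)
  if (length(cand) > 1L) {
    d_pair <- .comp_dist(new_model, m, M + 1L)
    d_oth <- vapply(setdiff(cand, M + 1L),
                    function(j) .comp_dist(new_model, m, j), numeric(1))
    admissible <- all(d_pair < d_oth)
  }
  n_ord <- .comp_pair_orderings(new_model, m, M + 1L)
  logg <- dbeta(w, 2, 2, log = TRUE) +
    sum(dnorm(bnew, comp$B[1, ], cfg$c, log = TRUE))
  lpr <- log(model$weights[m]) - logg + log(M) - log(M + 1) +
    (if (n_ord > 0L) log(n_ord) else -Inf)
  list(model = new_model, m = m, sibling = M + 1L, w = w,
       log_proposal_ratio = lpr, admissible = admissible)
}

#' Combine two mixture components with equal state counts
#'
#' Merges components m and m' state by state, weighting each state's rates,
#' coefficients and initial probability by the two components' stationary
#' probabilities for that state; the initial distribution is renormalized
#' and the mixture weights are summed.  The merged component keeps index m.
#'
#' @param model a [mixture_model()].
#' @param m,mp components to merge (must have the same number of states).
#' @param cfg a [move_config()].
#' @param prior a [prior_spec()].
#' @return List with the merged \code{model} and \code{log_proposal_ratio}.
#' @export
propose_component_combine <- function(model, m, mp, cfg, prior) {
  M1 <- model$M
  if (M1 < 2L) stop("component combine unavailable at M = 1")
  cm <- model$components[[m]]
  cp <- model$components[[mp]]
  if (cm$K != cp$K) stop("components must have the same number of states")
  K <- cm$K
  s1 <- stationary_distribution(cm$Q)
  s2 <- stationary_distribution(cp$Q)
  u <- s1 / (s1 + s2)
  Qm <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    Qm[i, j] <- u[i] * cm$Q[i, j] + (1 - u[i]) * cp$Q[i, j]
  Qm <- generator_matrix(Qm)
  Bm <- sweep(cm$B, 2, u, `*`) + sweep(cp$B, 2, 1 - u, `*`)
  pim <- u * cm$pi + (1 - u) * cp$pi
  pim <- pim / sum(pim)
  merged <- cthmm_model(pim, Qm, Bm, cm$family, cm$sigma)
  weights <- model$weights
  wsum <- weights[m] + weights[mp]
  comps <- model$components
  comps[[m]] <- merged
  comps <- comps[-mp]
  weights[m] <- wsum
  weights <- weights[-mp]
  new_model <- mixture_model(weights, comps)
  # implied reverse-split draws
  wstar <- model$weights[m] / wsum
  n_ord <- .comp_pair_orderings(model, m, mp)
  logg <- dbeta(wstar, 2, 2, log = TRUE) +
    sum(dnorm(cp$B[1, ], cm$B[1, ], cfg$c, log = TRUE))
  lpr <- logg - log(wsum) - (if (n_ord > 0L) log(n_ord) else -Inf) +
    log(M1) - log(M1 - 1)
  list(model = new_model, m = m, mp = mp, log_proposal_ratio = lpr)
}

# MH acceptance for component moves on the marginalized mixture likelihood
.component_log_acceptance <- function(prop, model, data, prior, cfg, type,
                                      ll = NULL) {
  M <- model$M
  ll_old <- mixture_marginal_loglik(model, data, ll)
  ll_new <- mixture_marginal_loglik(prop$model, data)
  lr <- (ll_new + log_prior_mixture(prop$model, prior)) -
    (ll_old + log_prior_mixture(model, prior))
  move_lr <- if (type == "split") {
    log(1 - b_of_m(M + 1L, cfg)) - log(b_of_m(M, cfg))
  } else {
    log(b_of_m(M - 1L, cfg)) - log(1 - b_of_m(M, cfg))
  }
  min(0, move_lr + prop$log_proposal_ratio + lr)
}

#' One full sweep of the clustering sampler
#'
#' The five-step schedule: (1) a trans-dimensional state move inside every
#' component, using only that component's currently assigned subjects;
#' (2) a component split/combine move on the marginalized mixture
#' likelihood; (3) membership resampling from the posterior membership
#' probabilities; (4) a fixed-dimension parameter sweep per component
#' (components with no subjects are thereby refreshed from the prior, since
#' their full conditionals reduce to it); (5) a conjugate Dirichlet update
#' of the mixture weights from the occupancy counts.
#'
#' @param state list with elements \code{mix} (a [mixture_model()]),
#'   \code{membership} (integer vector over subjects) and \code{scales}
#'   (per-component Metropolis scales).
#' @param data the full dataset.
#' @param prior a [prior_spec()].
#' @param cfg a [move_config()].
#' @param iter sweep index (drives Metropolis scale adaptation).
#' @param fix_sigma optionally hold the Gaussian dispersion fixed.
#' @return Updated state, with the sweep's move diagnostics attached.
#' @export
cluster_sweep <- function(state, data, prior, cfg, iter = 1L,
                          fix_sigma = NULL) {
  mix <- state$mix
  membership <- state$membership
  scales <- state$scales
  N <- data$n_subjects

  # (1) per-component state-dimension moves
  for (m in seq_len(mix$M)) {
    dm <- data_subset(data, which(membership == m))
    rj <- rj_state_step(mix$components[[m]], dm, prior, cfg)
    mix$components[[m]] <- rj$model
    scales[[m]] <- .resize_scales(scales[[m]], rj$model$K)
  }

  # (2) component split / combine on the marginalized likelihood
  llmat <- component_logliks(mix, data)
  move <- "split"; accepted <- FALSE; log_alpha <- -Inf
  if (cfg$Mmax <= 1L) {
    move <- "none"; log_alpha <- NA_real_
  } else if (runif(1) < b_of_m(mix$M, cfg)) {
    m <- sample.int(mix$M, 1L)
    prop <- propose_component_split(mix, m, cfg, prior)
    if (prop$admissible) {
      log_alpha <- .component_log_acceptance(prop, mix, data, prior, cfg,
                                             "split", llmat)
      if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
        accepted <- TRUE
        mix <- prop$model
        scales <- c(scales, scales[prop$m])
        llmat <- component_logliks(mix, data)
      }
    }
  } else {
    move <- "combine"
    m <- sample.int(mix$M, 1L)
    cand <- .same_k_candidates(mix, m)
    if (length(cand) > 0L) {
      d <- vapply(cand, function(j) .comp_dist(mix, m, j), numeric(1))
      mp <- cand[which.min(d)]
      prop <- tryCatch(propose_component_combine(mix, m, mp, cfg, prior),
                       error = function(e) NULL)
      if (!is.null(prop)) {
        log_alpha <- .component_log_acceptance(prop, mix, data, prior, cfg,
                                               "combine", llmat)
        if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
          accepted <- TRUE
          membership[membership == mp] <- m
          membership[membership > mp] <- membership[membership > mp] - 1L
          merged_at <- m - (m > mp)  # index shift past the removed slot
          newscale <- .resize_scales(unlist(scales[c(m, mp)]),
                                     prop$model$components[[merged_at]]$K)
          scales <- scales[-mp]
          scales[[merged_at]] <- newscale
          mix <- prop$model
          llmat <- component_logliks(mix, data)
        }
      }
    }
  }
  loglik <- mixture_marginal_loglik(mix, data, llmat)

  # (3) membership resampling
  if (N > 0L) {
    pr <- membership_posterior(mix, data, llmat)
    membership <- vapply(seq_len(N), function(n)
      sample.int(mix$M, 1L, prob = pr[n, ]), integer(1))
  }

  # (4) fixed-dimension sweeps per component (prior refresh when empty)
  for (m in seq_len(mix$M)) {
    dm <- data_subset(data, which(membership == m))
    sw <- sweep_fixed_k(mix$components[[m]], dm, prior,
                        ctrl = list(scales = scales[[m]], adapt = TRUE,
                                    iter = iter, fix_sigma = fix_sigma))
    mix$components[[m]] <- sw$model
    scales[[m]] <- sw$scales
  }

  # (5) conjugate weight update from occupancies
  occ <- tabulate(membership, nbins = mix$M)
  mix$weights <- rdirichlet1(prior$delta_mix + occ)

  list(mix = mix, membership = membership, scales = scales,
       move = move, accepted = accepted, log_alpha = log_alpha,
       loglik = loglik, occupancy = occ)
}

#' Model-based clustering with unknown numbers of clusters and states
#'
#' Runs the full clustering sampler from a one-component, one-state start,
#' recording per sweep the number of components M, the number of occupied
#' components M*, each component's state count, the weights and the
#' marginalized mixture log-likelihood.
#'
#' @inheritParams fit_cthmm_rj
#' @return An object of class \code{cthmm_cluster_fit}.
#' @export
fit_cthmm_cluster <- function(data, family = c("normal", "poisson"),
                              prior = prior_spec(), cfg = move_config(),
                              iterations = 2500L,
                              burnin = min(500L, iterations %/% 4L),
                              fix_sigma = NULL, verbose = FALSE) {
  family <- match.arg(family)
  comp0 <- .init_model(data, 1L, family, prior, fix_sigma)
  state <- list(mix = mixture_model(1, list(comp0)),
                membership = rep(1L, data$n_subjects),
                scales = list(rep(0.3, 1L)))
  trace <- data.frame(iter = seq_len(iterations), M = NA_integer_,
                      Mstar = NA_integer_, move = NA_character_,
                      accepted = NA, log_alpha = NA_real_,
                      loglik = NA_real_)
  Ks <- vector("list", iterations)
  Ws <- vector("list", iterations)
  memberships <- matrix(NA_integer_, iterations, data$n_subjects)
  for (it in seq_len(iterations)) {
    state <- cluster_sweep(state, data, prior, cfg, iter = it,
                           fix_sigma = fix_sigma)
    trace$M[it] <- state$mix$M
    trace$Mstar[it] <- max(1L, length(unique(state$membership)))
    trace$move[it] <- state$move
    trace$accepted[it] <- state$accepted
    trace$log_alpha[it] <- state$log_alpha
    trace$loglik[it] <- state$loglik
    Ks[[it]] <- vapply(state$mix$components, `[[`, 0L, "K")
    Ws[[it]] <- state$mix$weights
    if (data$n_subjects > 0L) memberships[it, ] <- state$membership
    if (verbose && it %% 250L == 0L)
      message(sprintf("sweep %d / %d (M = %d, M* = %d)", it, iterations,
                      state$mix$M, trace$Mstar[it]))
  }
  structure(list(trace = trace, Ks = Ks, weights = Ws,
                 memberships = memberships, family = family, prior = prior,
                 cfg = cfg, iterations = iterations, burnin = burnin,
                 final_state = state),
            class = "cthmm_cluster_fit")
}

#' Posterior distribution of the number of components or clusters
#'
#' @param fit a \code{cthmm_cluster_fit}.
#' @param which \code{"Mstar"} (occupied components, i.e. clusters) or
#'   \code{"M"} (mixture components).
#' @param burnin sweeps to drop.
#' @return Data frame with the count and its posterior probability.
#' @export
m_posterior <- function(fit, which = c("Mstar", "M"), burnin = fit$burnin) {
  which <- match.arg(which)
  v <- fit$trace[[which]][fit$trace$iter > burnin]
  tab <- table(factor(v, levels = seq_len(max(v))))
  out <- data.frame(as.integer(names(tab)), as.numeric(tab) / length(v))
  names(out) <- c(which, "prob")
  out
}

#' Cluster assignment summary
#'
#' Conditional on the sweeps whose number of occupied components equals the
#' posterior mode, assigns each subject its modal component and reports the
#' assignment probability, the cluster sizes and each cluster's modal state
#' count.
#'
#' @param fit a \code{cthmm_cluster_fit}.
#' @param burnin sweeps to drop.
#' @return List with modal \code{Mstar}, a per-subject membership table and
#'   per-cluster modal state counts.
#' @export
cluster_summary <- function(fit, burnin = fit$burnin) {
  mp <- m_posterior(fit, "Mstar", burnin)
  mstar <- mp$Mstar[which.max(mp$prob)]
  sel <- which(fit$trace$iter > burnin & fit$trace$Mstar == mstar)
  mm <- fit$memberships[sel, , drop = FALSE]
  modal <- apply(mm, 2, function(x) {
    tb <- table(x)
    as.integer(names(tb)[which.max(tb)])
  })
  probs <- vapply(seq_along(modal), function(n) mean(mm[, n] == modal[n]),
                  numeric(1))
  ks <- vapply(sort(unique(modal)), function(cl) {
    kk <- unlist(lapply(sel, function(it) {
      comp <- fit$memberships[it, which(modal == cl)[1]]
      fit$Ks[[it]][comp]
    }))
    tb <- table(kk)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
  members <- data.frame(subject = seq_along(modal), cluster = modal,
                        prob = probs)
  list(Mstar = mstar, members = members,
       cluster_sizes = as.integer(table(factor(modal, sort(unique(modal))))),
       modal_states = ks, n_sweeps = length(sel))
}

#' Write the final membership table as CSV
#'
#' Columns: subject identifier, modal cluster, posterior assignment
#' probability.
#'
#' @param fit a \code{cthmm_cluster_fit}.
#' @param data the dataset the fit was run on (for subject identifiers).
#' @param path output file.
#' @export
write_membership_csv <- function(fit, data, path) {
  cs <- cluster_summary(fit)
  out <- cs$members
  out$subject <- data$subject_ids[out$subject]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
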