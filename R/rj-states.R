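#' Configuration of the trans-dimensional moves
#'
#' @param b_split probability of proposing a split of a hidden state (the
#'   combine move has probability \code{1 - b_split}); at K = 1 a split is
#'   forced and at \code{Kmax} a combine is forced, with the move
#'   probabilities entering the acceptance ratio accordingly.
#' @param c standard deviation of the intercept perturbation in the centered
#'   split proposal.
#' @param Kmax hard cap on the number of states.
#' @param b_split_m probability of proposing a component split in the
#'   clustering sampler (the component combine probability is
#'   \code{1 - b_split_m}; default 0.3, i.e. combine probability 0.7).
#' @param Mmax hard cap on the number of mixture components.
#' @return An object of class \code{move_config}.
#' @export
move_config <- function(b_split = 0.5, c = 1, Kmax = 10L,
                        b_split_m = 0.3, Mmax = 15L) {
  stopifnot(b_split > 0, b_split < 1, c >= 0, Kmax >= 1,
            b_split_m > 0, b_split_m < 1, Mmax >= 1)
  structure(list(b_split = b_split, c = c, Kmax = as.integer(Kmax),
                 b_split_m = b_split_m, Mmax = as.integer(Mmax)),
            class = "move_config")
}

# split probability at a given K, honouring the boundaries
b_of <- function(K, cfg) {
  if (cfg$Kmax <= 1L) 0 else if (K <= 1L) 1 else if (K >= cfg$Kmax) 0 else
    cfg$b_split
}

# relabel states of a model by `perm`: new index i holds old state perm[i]
permute_model <- function(model, perm) {
  cthmm_model(model$pi[perm], model$Q[perm, perm, drop = FALSE],
              model$B[, perm, drop = FALSE], model$family, model$sigma)
}

# L1 distance between coefficient columns
.col_l1 <- function(B, a, b) sum(abs(B[, a] - B[, b]))

#' Choose the pair of states for a combine move
#'
#' Picks a state \code{k} uniformly at random and pairs it with the state
#' whose coefficient column is closest in L1 distance (smallest index on
#' ties).
#'
#' @param B D x K coefficient matrix, K >= 2.
#' @param k optionally force the first state of the pair (default: uniform).
#' @return Integer vector \code{c(k, k')}.
#' @export
select_combine_pair <- function(B, k = NULL) {
  K <- ncol(B)
  if (K < 2L) stop("combine move unavailable at K = 1")
  if (is.null(k)) k <- sample.int(K, 1L)
  others <- setdiff(seq_len(K), k)
  d <- vapply(others, function(j) .col_l1(B, k, j), numeric(1))
  c(k, others[which.min(d)])
}

#' Early adjacency check for a split proposal
#'
#' A split of state \code{k} with new sibling \code{k'} is admissible only
#' if the sibling is strictly the nearest state to \code{k} in L1 distance
#' on the coefficient columns; otherwise the reverse combine move could not
#' select the pair and the split is rejected outright.
#'
#' @param B_new proposed (K+1)-column coefficient matrix.
#' @param k,kp the split state and its new sibling.
#' @return Logical flag.
#' @export
check_split_adjacency <- function(B_new, k, kp) {
  K1 <- ncol(B_new)
  if (K1 <= 2L) return(TRUE)
  d_pair <- .col_l1(B_new, k, kp)
  others <- setdiff(seq_len(K1), c(k, kp))
  all(d_pair < vapply(others, function(j) .col_l1(B_new, k, j), numeric(1)))
}

# number of ordered selections (first uniform, partner by argmin L1) that
# produce the unordered pair {k, kp}; in {0, 1, 2}
.pair_orderings <- function(B, k, kp) {
  n <- 0L
  for (o in list(c(k, kp), c(kp, k))) {
    others <- setdiff(seq_len(ncol(B)), o[1])
    d <- vapply(others, function(j) .col_l1(B, o[1], j), numeric(1))
    if (others[which.min(d)] == o[2]) n <- n + 1L
  }
  n
}

#' Centered split proposal for a hidden state
#'
#' Splits state \code{k} into two states using the stationary-preserving
#' construction: outgoing rates are copied to both children, incoming rates
#' are divided by Beta(2,2) weights, the two new cross rates are drawn from
#' the Gamma prior, the initial probability is divided by a Beta(2,2)
#' weight, and the new state's intercept is a N(beta, c^2) perturbation
#' (other coefficient rows are copied).  The returned log proposal ratio is
#' the Jacobian-times-selection factor over the proposal density, i.e. the
#' non-posterior part of the acceptance ratio beyond the move probabilities.
#'
#' @param model current [cthmm_model()] with K states.
#' @param k state to split.
#' @param cfg a [move_config()].
#' @param prior a [prior_spec()].
#' @return List with the proposed \code{model} (K+1 states; the new sibling
#'   has index K+1), the drawn quantities, \code{log_proposal_ratio} and the
#'   adjacency flag \code{admissible}.
#' @export
propose_split <- function(model, k, cfg, prior) {
  K <- model$K
  if (K >= cfg$Kmax) stop("split unavailable at Kmax")
  perm <- c(setdiff(seq_len(K), k), k)
  mp <- permute_model(model, perm)
  wi <- if (K > 1L) rbeta(K - 1L, 2, 2) else numeric(0)
  w <- rbeta(1, 2, 2)
  qcross <- rgamma(2, shape = prior$q_shape, rate = prior$q_rate)
  bnew <- rnorm(1, mp$B[1, K], cfg$c)

  Qn <- matrix(0, K + 1L, K + 1L)
  if (K > 1L) {
    Qn[seq_len(K - 1L), seq_len(K - 1L)] <- mp$Q[seq_len(K - 1L), seq_len(K - 1L)]
    Qn[K, seq_len(K - 1L)] <- mp$Q[K, seq_len(K - 1L)]
    Qn[K + 1L, seq_len(K - 1L)] <- mp$Q[K, seq_len(K - 1L)]
    Qn[seq_len(K - 1L), K] <- wi * mp$Q[seq_len(K - 1L), K]
    Qn[seq_len(K - 1L), K + 1L] <- (1 - wi) * mp$Q[seq_len(K - 1L), K]
  }
  Qn[K, K + 1L] <- qcross[1]
  Qn[K + 1L, K] <- qcross[2]
  Qn <- generator_matrix(Qn)
  Bn <- cbind(mp$B, mp$B[, K])
  Bn[1, K + 1L] <- bnew
  pin <- c(mp$pi[-K], w * mp$pi[K], (1 - w) * mp$pi[K])
  big <- cthmm_model(pin, Qn, Bn, model$family, model$sigma)
  final_perm <- order(c(perm, K + 1L))
  model_new <- permute_model(big, final_perm)

  admissible <- check_split_adjacency(model_new$B, k, K + 1L)
  n_ord <- .pair_orderings(model_new$B, k, K + 1L)
  logJ <- sum(log(mp$Q[seq_len(K - 1L), K])) + log(mp$pi[K])
  logg <- sum(dbeta(wi, 2, 2, log = TRUE)) + dbeta(w, 2, 2, log = TRUE) +
    sum(dgamma(qcross, shape = prior$q_shape, rate = prior$q_rate, log = TRUE)) +
    dnorm(bnew, mp$B[1, K], cfg$c, log = TRUE)
  lpr <- logJ - logg + log(K) - log(K + 1) +
    (if (n_ord > 0L) log(n_ord) else -Inf)
  list(model = model_new, k = k, sibling = K + 1L, w = wi, w_pi = w,
       q_cross = qcross, beta_new = bnew, log_proposal_ratio = lpr,
       admissible = admissible)
}

#' Deterministic combine of two hidden states
#'
#' Merges states \code{k} and \code{kp}: outgoing rates and coefficient
#' columns are averaged with the states' stationary-probability weights,
#' incoming rates are summed, the two cross rates are discarded and the
#' initial probabilities are summed.  The stationary law of the merged
#' generator satisfies \eqn{s_j = s'_j} off the pair and
#' \eqn{s_{merged} = s'_k + s'_{k'}}.  Also returns the reverse-move log
#' ratio (the exact negative of the matching split factor).
#'
#' @param model current [cthmm_model()] with K+1 states.
#' @param k,kp states to merge (the merged state keeps index \code{k}).
#' @param cfg a [move_config()].
#' @param prior a [prior_spec()].
#' @return List with the merged \code{model} (K states) and
#'   \code{log_proposal_ratio}.
#' @export
propose_combine <- function(model, k, kp, cfg, prior) {
  K1 <- model$K
  if (K1 < 2L) stop("combine unavailable at K = 1")
  K <- K1 - 1L
  s <- stationary_distribution(model$Q)
  perm <- c(setdiff(seq_len(K1), c(k, kp)), k, kp)
  mp <- permute_model(model, perm)
  sp <- s[perm]
  u0 <- sp[K] / (sp[K] + sp[K1])

  Qm <- matrix(0, K, K)
  if (K > 1L) {
    Qm[seq_len(K - 1L), seq_len(K - 1L)] <- mp$Q[seq_len(K - 1L), seq_len(K - 1L)]
    Qm[K, seq_len(K - 1L)] <- u0 * mp$Q[K, seq_len(K - 1L)] +
      (1 - u0) * mp$Q[K1, seq_len(K - 1L)]
    Qm[seq_len(K - 1L), K] <- mp$Q[seq_len(K - 1L), K] + mp$Q[seq_len(K - 1L), K1]
  }
  Qm <- generator_matrix(Qm)
  Bm <- cbind(mp$B[, seq_len(K - 1L), drop = FALSE],
              u0 * mp$B[, K] + (1 - u0) * mp$B[, K1])
  pim <- c(mp$pi[seq_len(K - 1L)], mp$pi[K] + mp$pi[K1])
  merged <- cthmm_model(pim, Qm, Bm, model$family, model$sigma)
  labels <- c(setdiff(seq_len(K1), c(k, kp)), k)
  model_new <- permute_model(merged, order(labels))

  # implied split draws that would reverse this merge
  wi <- if (K > 1L) {
    tot <- mp$Q[seq_len(K - 1L), K] + mp$Q[seq_len(K - 1L), K1]
    ifelse(tot > 0, mp$Q[seq_len(K - 1L), K] / tot, 0.5)
  } else numeric(0)
  w <- mp$pi[K] / (mp$pi[K] + mp$pi[K1])
  qcross <- c(mp$Q[K, K1], mp$Q[K1, K])
  n_ord <- .pair_orderings(model$B, k, kp)
  logJ <- sum(log(Qm[seq_len(K - 1L), K])) + log(pim[K])
  logg <- sum(dbeta(wi, 2, 2, log = TRUE)) + dbeta(w, 2, 2, log = TRUE) +
    sum(dgamma(qcross, shape = prior$q_shape, rate = prior$q_rate, log = TRUE)) +
    dnorm(mp$B[1, K1], mp$B[1, K], cfg$c, log = TRUE)
  lpr <- logg - logJ - (if (n_ord > 0L) log(n_ord) else -Inf) +
    log(K1) - log(K)
  list(model = model_new, k = k, kp = kp, log_proposal_ratio = lpr)
}

# posterior part of the trans-dimensional ratio, log p(K_new,.)-log p(K_old,.)
.log_r <- function(model_new, model_old, data, prior, ll_new = NULL,
                   ll_old = NULL) {
  if (is.null(ll_new)) ll_new <- .forward_loglik(model_new, data)
  if (is.null(ll_old)) ll_old <- .forward_loglik(model_old, data)
  lr <- (ll_new + log_prior_theta(model_new, prior) +
           log_p0_count(model_new$K, prior$k_prior, prior$Kmax)) -
    (ll_old + log_prior_theta(model_old, prior) +
       log_p0_count(model_old$K, prior$k_prior, prior$Kmax))
  attr(lr, "ll_new") <- ll_new
  lr
}

#' Log acceptance probability of a split move
#'
#' Combines the move probabilities, the proposal/Jacobian factor of the
#' centered split and the posterior ratio evaluated with the forward
#' marginal likelihood.
#'
#' @param proposal output of [propose_split()].
#' @param model current model (K states).
#' @param data dataset (may be empty for prior-only chains).
#' @param prior a [prior_spec()].
#' @param cfg a [move_config()].
#' @param ll_current optional cached forward log-likelihood of \code{model}.
#' @return log acceptance probability (<= 0), with the proposed model's
#'   forward log-likelihood attached as attribute \code{"loglik_new"}.
#' @export
split_log_acceptance <- function(proposal, model, data, prior, cfg,
                                 ll_current = NULL) {
  K <- model$K
  lr <- .log_r(proposal$model, model, data, prior, ll_old = ll_current)
  la <- min(0, log(1 - b_of(K + 1L, cfg)) - log(b_of(K, cfg)) +
              proposal$log_proposal_ratio + as.numeric(lr))
  attr(la, "loglik_new") <- attr(lr, "ll_new")
  la
}

#' Log acceptance probability of a combine move
#'
#' @param proposal output of [propose_combine()].
#' @param model current model (K+1 states).
#' @inheritParams split_log_acceptance
#' @return log acceptance probability (<= 0), with attribute
#'   \code{"loglik_new"}.
#' @export
combine_log_acceptance <- function(proposal, model, data, prior, cfg,
                                   ll_current = NULL) {
  K1 <- model$K
  lr <- .log_r(proposal$model, model, data, prior, ll_old = ll_current)
  la <- min(0, log(b_of(K1 - 1L, cfg)) - log(1 - b_of(K1, cfg)) +
              proposal$log_proposal_ratio + as.numeric(lr))
  attr(la, "loglik_new") <- attr(lr, "ll_new")
  la
}

#' One trans-dimensional step on the number of hidden states
#'
#' With probability \code{b_split} proposes a centered split (forced at
#' K = 1), otherwise a combine of the closest coefficient pair (forced at
#' \code{Kmax}); applies the early adjacency rejection and the
#' Metropolis-Hastings acceptance on the forward marginal likelihood.
#'
#' @param model current [cthmm_model()].
#' @param data dataset (empty data gives a flat likelihood, so the chain
#'   targets the prior: the standard trans-dimensional correctness check).
#' @param prior a [prior_spec()].
#' @param cfg a [move_config()].
#' @param ll_current optional cached forward log-likelihood.
#' @return List with the (possibly unchanged) \code{model}, its forward
#'   \code{loglik}, \code{move}, \code{accepted} and \code{log_alpha}.
#' @export
rj_state_step <- function(model, data, prior, cfg, ll_current = NULL) {
  K <- model$K
  if (is.null(ll_current)) ll_current <- .forward_loglik(model, data)
  if (cfg$Kmax <= 1L)  # dimension is pinned; no move available
    return(list(model = model, loglik = ll_current, move = "none",
                accepted = FALSE, log_alpha = NA_real_))
  if (runif(1) < b_of(K, cfg)) {
    k <- sample.int(K, 1L)
    prop <- propose_split(model, k, cfg, prior)
    if (!prop$admissible)
      return(list(model = model, loglik = ll_current, move = "split",
                  accepted = FALSE, log_alpha = -Inf))
    la <- split_log_acceptance(prop, model, data, prior, cfg, ll_current)
    move <- "split"
  } else {
    pair <- select_combine_pair(model$B)
    prop <- tryCatch(propose_combine(model, pair[1], pair[2], cfg, prior),
                     error = function(e) NULL)
    if (is.null(prop))
      return(list(model = model, loglik = ll_current, move = "combine",
                  accepted = FALSE, log_alpha = -Inf))
    la <- combine_log_acceptance(prop, model, data, prior, cfg, ll_current)
    move <- "combine"
  }
  if (is.finite(la) && log(runif(1)) < la) {
    list(model = prop$model, loglik = attr(la, "loglik_new"), move = move,
         accepted = TRUE, log_alpha = as.numeric(la))
  } else {
    list(model = model, loglik = ll_current, move = move, accepted = FALSE,
         log_alpha = as.numeric(la))
  }
}
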