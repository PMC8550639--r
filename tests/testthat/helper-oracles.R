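# Independent oracles used across the suite.  Each is deliberately written
# against a different route than the implementation it checks.

# stationary law via the eigen decomposition of t(Q) (null-space solve)
oracle_stationary <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  s <- Re(e$vectors[, i])
  s / sum(s)
}

# forward marginal likelihood by exhaustive enumeration over all K^T latent
# skeletons of one subject
oracle_forward_enum <- function(model, times, outcomes, Z) {
  K <- model$K
  T <- length(times)
  P <- lapply(seq_len(T - 1),
              function(t) transition_probability(model$Q, times[t + 1] - times[t]))
  dens <- function(o, z, k) {
    exp(glm_logdensity(o, z, model$B[, k], model$family, model$sigma))
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  tot <- 0
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    p <- model$pi[s[1]] * dens(outcomes[1], Z[1, ], s[1])
    for (t in seq_len(T - 1))
      p <- p * P[[t]][s[t], s[t + 1]] * dens(outcomes[t + 1], Z[t + 1, ], s[t + 1])
    tot <- tot + p
  }
  log(tot)
}

# pmf of the number of *actual* jumps of an endpoint-conditioned CTMC over
# [0, t], by uniformization truncated at nmax virtual jumps, with a dynamic
# program over (position, state, changes so far)
oracle_jump_count_pmf <- function(Q, a, b, t, nmax = 30L) {
  K <- nrow(Q)
  R <- max(-diag(Q))
  Pu <- diag(K) + Q / R
  pab <- transition_probability(Q, t)[a, b]
  pmf <- rep(0, nmax + 1L)  # real jump counts 0..nmax
  for (n in 0:nmax) {
    wn <- dpois(n, R * t)
    if (n == 0L) {
      if (a == b) pmf[1] <- pmf[1] + wn
      next
    }
    # f[state, changes+1] after j virtual jumps, starting from a
    f <- matrix(0, K, n + 1L)
    f[a, 1] <- 1
    for (j in seq_len(n)) {
      g <- matrix(0, K, n + 1L)
      for (s in seq_len(K)) for (cc in seq_len(n + 1L)) {
        if (f[s, cc] == 0) next
        for (v in seq_len(K)) {
          dc <- if (v == s) 0L else 1L
          if (cc + dc <= n + 1L)
            g[v, cc + dc] <- g[v, cc + dc] + f[s, cc] * Pu[s, v]
        }
      }
      f <- g
    }
    pmf[seq_len(n + 1L)] <- pmf[seq_len(n + 1L)] + wn * f[b, ]
  }
  pmf / pab
}

# complete-data log-likelihood assembled by hand for explicit paths
oracle_complete_loglik <- function(model, paths, subjects) {
  tot <- 0
  for (n in seq_along(paths)) {
    p <- paths[[n]]
    sub <- subjects[[n]]
    ns <- length(p$states)
    tot <- tot + log(model$pi[p$states[1]])
    ends <- c(p$times[-1], p$horizon)
    for (i in seq_len(ns)) {
      tot <- tot + model$Q[p$states[i], p$states[i]] * (ends[i] - p$times[i])
      if (i < ns) tot <- tot + log(model$Q[p$states[i], p$states[i + 1]])
    }
    for (t in seq_along(sub$times)) {
      k <- p$states[max(which(p$times <= sub$times[t] + 1e-12))]
      tot <- tot + glm_logdensity(sub$outcomes[t], sub$Z[t, ], model$B[, k],
                                  model$family, model$sigma)
    }
  }
  tot
}

# independent term-by-term recomputation of the split log proposal ratio
oracle_split_lpr <- function(model, k, prop, cfg, prior) {
  K <- model$K
  incoming <- model$Q[setdiff(seq_len(K), k), k]
  logJ <- sum(log(incoming)) + log(model$pi[k])
  logg <- sum(dbeta(prop$w, 2, 2, log = TRUE)) +
    dbeta(prop$w_pi, 2, 2, log = TRUE) +
    sum(dgamma(prop$q_cross, shape = prior$q_shape, rate = prior$q_rate,
               log = TRUE)) +
    dnorm(prop$beta_new, model$B[1, k], cfg$c, log = TRUE)
  Bn <- prop$model$B
  n_ord <- 0L
  for (o in list(c(k, K + 1L), c(K + 1L, k))) {
    others <- setdiff(seq_len(K + 1L), o[1])
    d <- vapply(others, function(j) sum(abs(Bn[, o[1]] - Bn[, j])), numeric(1))
    if (others[which.min(d)] == o[2]) n_ord <- n_ord + 1L
  }
  logJ - logg + log(K) - log(K + 1) + log(n_ord)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# batch-means Monte Carlo standard error for a (possibly correlated) chain
batch_se <- function(x, nbatch = floor(sqrt(length(x)))) {
  bs <- floor(length(x) / nbatch)
  means <- vapply(seq_len(nbatch),
                  function(i) mean(x[((i - 1) * bs + 1):(i * bs)]), numeric(1))
  sd(means) / sqrt(nbatch)
}

# small random irreducible generator
random_generator <- function(K, rate = 1) {
  M <- matrix(rgamma(K * K, 1, 1 / rate), K, K)
  generator_matrix(M)
}

# tiny deterministic toy dataset builder
toy_data <- function(times, outcomes, Z = NULL) {
  df <- data.frame(subject = rep(seq_along(times), lengths(times)),
                   time = unlist(times), outcome = unlist(outcomes))
  if (!is.null(Z)) {
    Zm <- do.call(rbind, Z)
    colnames(Zm) <- paste0("z", seq_len(ncol(Zm)))
    df <- cbind(df, as.data.frame(Zm))
  }
  as_cthmm_data(df)
}
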