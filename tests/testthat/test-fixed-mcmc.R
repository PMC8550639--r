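# Fixed-K sampler components: conjugate updates, latent-path imputation,
# parameter recovery.

test_that("update_Q is the conjugate Gamma full conditional", {
  set.seed(31)
  pr <- prior_spec(q_shape = 1.5, q_rate = 2.5)
  # no data: prior recovery
  stats0 <- list(ntrans = matrix(0, 2, 2), dwell = c(0, 0))
  draws <- replicate(20000, update_Q(stats0, pr)[1, 2])
  expect_lt(abs(mean(draws) - 1.5 / 2.5),
            3 * sd(draws) / sqrt(length(draws)))
  # with sufficient statistics: mean (a + N) / (b + T)
  stats <- list(ntrans = matrix(c(0, 4, 7, 0), 2, 2, byrow = TRUE),
                dwell = c(3.2, 5.5))
  qs <- replicate(20000, update_Q(stats, pr))
  m12 <- mean(qs[1, 2, ]); m21 <- mean(qs[2, 1, ])
  expect_lt(abs(m12 - (1.5 + 4) / (2.5 + 3.2)),
            3 * sd(qs[1, 2, ]) / sqrt(20000))
  expect_lt(abs(m21 - (1.5 + 7) / (2.5 + 5.5)),
            3 * sd(qs[2, 1, ]) / sqrt(20000))
  expect_equal(rowSums(update_Q(stats, pr)), c(0, 0), tolerance = 1e-12)
  expect_equal(update_Q(list(ntrans = matrix(0, 1, 1), dwell = 0), pr),
               matrix(0, 1, 1))
})

test_that("update_pi is the conjugate Dirichlet full conditional", {
  set.seed(32)
  pr <- prior_spec(pi_conc = 1)
  d0 <- replicate(20000, update_pi(c(0, 0), pr)[1])
  expect_lt(abs(mean(d0) - 0.5), 3 * sd(d0) / sqrt(length(d0)))
  d1 <- replicate(20000, update_pi(c(10, 0), pr)[1])
  expect_lt(abs(mean(d1) - 11 / 12), 3 * sd(d1) / sqrt(length(d1)))
  expect_equal(sum(update_pi(c(3, 1, 7), pr)), 1, tolerance = 1e-12)
})

test_that("normal-family update_B matches the OLS oracle and prior draws", {
  set.seed(33)
  n <- 60
  Z <- cbind(1, rnorm(n))
  beta_true <- c(1.5, -0.8)
  o <- as.vector(Z %*% beta_true) + rnorm(n)
  df <- data.frame(subject = 1, time = seq(0, by = 0.1, length.out = n),
                   outcome = o, z1 = 1, z2 = Z[, 2])
  dat <- as_cthmm_data(df)
  m <- cthmm_model(1, matrix(0, 1, 1), matrix(0, 2, 1), "normal", sigma = 1)
  pr <- prior_spec(beta_sd = 1e4)  # effectively flat
  skel <- rep(1L, n)
  draws <- replicate(4000, update_B(m, skel, dat, pr, fix_sigma = 1)$B[, 1])
  ols <- qr.solve(Z, o)
  for (j in 1:2)
    expect_lt(abs(mean(draws[j, ]) - ols[j]),
              3 * sd(draws[j, ]) / sqrt(ncol(draws)) + 1e-4)
  # a state with no observations draws from the prior
  m2 <- cthmm_model(c(.5, .5), generator_matrix(matrix(c(0, 1, 1, 0), 2, 2)),
                    matrix(0, 2, 2), "normal", sigma = 1)
  pr2 <- prior_spec(beta_mean = 0, beta_sd = 2)
  d2 <- replicate(5000, update_B(m2, skel, dat, pr2, fix_sigma = 1)$B[1, 2])
  expect_lt(abs(mean(d2) - 0), 4 * 2 / sqrt(5000))
  expect_lt(abs(sd(d2) - 2), 0.15)
})

test_that("poisson update_B targets its conditional (conjugate-free MH)", {
  set.seed(34)
  n <- 80
  o <- rpois(n, 4)
  df <- data.frame(subject = 1, time = seq(0, by = 0.1, length.out = n),
                   outcome = o)
  dat <- as_cthmm_data(df)
  m <- cthmm_model(1, matrix(0, 1, 1), matrix(log(4), 1, 1), "poisson")
  pr <- prior_spec(beta_prior = "poisson-rate", rate_shape = 10, rate_rate = 10)
  # long MH run from the stationary region: mean of exp(beta) should match
  # the Gamma(10 + sum o, 10 + n) conjugate posterior mean of the rate
  b <- m$B
  acc <- 0
  vals <- numeric(5000)
  cur <- m
  for (i in seq_len(5000)) {
    up <- update_B(cur, rep(1L, n), dat, pr, scales = 0.2)
    cur$B <- up$B
    vals[i] <- exp(cur$B[1, 1])
    acc <- acc + isTRUE(up$accept[1])
  }
  post_mean <- (10 + sum(o)) / (10 + n)
  expect_lt(abs(mean(vals[-(1:500)]) - post_mean), 4 * batch_se(vals[-(1:500)]))
  expect_gt(acc / 5000, 0.1)
})

test_that("imputation is exact: K = 1, enumeration oracle, degenerate limit", {
  set.seed(35)
  # K = 1: deterministic single-state path
  dat <- toy_data(list(c(0, 1, 2)), list(c(0.1, 0.4, -0.2)))
  m1 <- cthmm_model(1, matrix(0, 1, 1), 0, "normal", sigma = 1)
  imp <- impute_paths(m1, dat, keep_paths = TRUE)
  expect_equal(imp$skeleton, rep(1L, 3))
  expect_equal(imp$paths[[1]]$states, 1L)
  expect_equal(imp$dwell, 2)

  # K = 2, T = 3: skeleton law vs exact conditional over the 8 sequences
  Q <- generator_matrix(matrix(c(0, 0.9, 0.7, 0), 2, 2, byrow = TRUE))
  m <- cthmm_model(c(0.6, 0.4), Q, c(-1, 1), "normal", sigma = 1.5)
  times <- c(0, 0.8, 1.7); o <- c(-0.5, 0.9, -1.2)
  dat2 <- toy_data(list(times), list(o))
  P <- lapply(1:2, function(t) transition_probability(Q, times[t + 1] - times[t]))
  f <- vapply(1:2, function(k) dnorm(o, m$B[1, k], m$sigma), numeric(3))
  seqs <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  exact <- apply(seqs, 1, function(s)
    m$pi[s[1]] * f[1, s[1]] * P[[1]][s[1], s[2]] * f[2, s[2]] *
      P[[2]][s[2], s[3]] * f[3, s[3]])
  exact <- exact / sum(exact)
  nrep <- 50000
  idx <- integer(nrep)
  for (i in seq_len(nrep)) {
    sk <- impute_paths(m, dat2)$skeleton
    idx[i] <- which(seqs[, 1] == sk[1] & seqs[, 2] == sk[2] & seqs[, 3] == sk[3])
  }
  obs <- tabulate(idx, nbins = 8)
  suppressWarnings(pval <- stats::chisq.test(obs, p = exact)$p.value)
  expect_gt(pval, 0.001)

  # near-noiseless emissions pin the skeleton to the data-implied states
  m3 <- cthmm_model(c(0.5, 0.5), Q, c(-1, 1), "normal", sigma = 1e-3)
  o3 <- c(-1, 1, 1, -1)
  dat3 <- toy_data(list(c(0, 0.5, 1.1, 2)), list(o3))
  sk3 <- impute_paths(m3, dat3)$skeleton
  expect_equal(sk3, c(1L, 2L, 2L, 1L))
})

test_that("imputed sufficient statistics are consistent with the full paths", {
  set.seed(36)
  sc <- builtin_scenario("SIM2-3state-intercept", "normal", 1)
  sim <- simulate_cthmm(sc, n_subjects = 12)
  m <- cthmm_model(sc$clusters[[1]]$pi, sc$clusters[[1]]$Q,
                   sc$clusters[[1]]$B, "normal", sigma = 1)
  imp <- impute_paths(m, sim$data, keep_paths = TRUE)
  expect_equal(sum(imp$init_counts), 12L)
  expect_true(all(diag(imp$ntrans) == 0))
  dwell <- rep(0, 3); ntr <- matrix(0, 3, 3); init <- rep(0L, 3)
  for (n in seq_len(12)) {
    p <- imp$paths[[n]]
    ends <- c(p$times[-1], p$horizon)
    for (i in seq_along(p$states))
      dwell[p$states[i]] <- dwell[p$states[i]] + ends[i] - p$times[i]
    if (length(p$states) > 1)
      for (i in seq_len(length(p$states) - 1))
        ntr[p$states[i], p$states[i + 1]] <- ntr[p$states[i], p$states[i + 1]] + 1
    init[p$states[1]] <- init[p$states[1]] + 1L
  }
  expect_equal(imp$dwell, dwell, tolerance = 1e-9)
  expect_equal(imp$ntrans, ntr)
  expect_equal(imp$init_counts, init)
})

test_that("fixed-K sampler recovers well-separated state means", {
  set.seed(37)
  sc <- builtin_scenario("SIM2-3state-intercept", "normal", 1)
  sim <- simulate_cthmm(sc, n_subjects = 200)
  pr <- prior_spec(beta_sd = 1)
  fit <- fit_cthmm_fixed(sim$data, K = 3, family = "normal", prior = pr,
                         iterations = 800, burnin = 200)
  keep <- 201:800
  ints <- t(apply(fit$draws$B[keep, 1, ], 1, sort))
  pm <- colMeans(ints)
  psd <- apply(ints, 2, sd)
  expect_true(all(abs(pm - c(-4, 0, 5)) < 3 * psd))
  # sigma is recovered too
  expect_lt(abs(mean(fit$draws$sigma[keep]) - 1), 0.05)
})
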