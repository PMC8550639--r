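# Finite-mixture clustering: marginalized likelihood, membership law,
# component split/combine moves and the sweep schedule.

rand_mix <- function(M, Ks = sample(1:3, M, replace = TRUE), D = 1) {
  comps <- lapply(Ks, function(K)
    cthmm_model(rdirichlet1(rep(2, K)), random_generator(K),
                matrix(rnorm(D * K), D, K), "normal", 1))
  mixture_model(rdirichlet1(rep(2, M)), comps)
}

test_that("membership posterior: degenerate and symmetric cases", {
  set.seed(51)
  dat <- toy_data(list(c(0, 0.5, 1.2), c(0, 1, 2)),
                  list(c(0.3, -0.4, 0.8), c(1.1, 0.2, -0.6)))
  m1 <- rand_mix(1)
  expect_equal(as.vector(membership_posterior(m1, dat)), c(1, 1))
  # identical components: posterior equals the weights
  comp <- rand_mix(1)$components[[1]]
  mix <- mixture_model(c(0.3, 0.7), list(comp, comp))
  post <- membership_posterior(mix, dat)
  expect_equal(post, matrix(c(0.3, 0.7), 2, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rows always normalize for random mixtures
  for (rep in 1:5) {
    mm <- rand_mix(3)
    expect_equal(rowSums(membership_posterior(mm, dat)), c(1, 1),
                 tolerance = 1e-12)
  }
})

test_that("mixture marginal likelihood: reduction, invariance, hand check", {
  set.seed(52)
  dat <- toy_data(list(c(0, 0.5), c(0, 1), c(0, 0.4)),
                  list(c(0.3, -0.4), c(1.1, 0.2), c(-2, 0.5)))
  m1 <- rand_mix(1)
  expect_equal(mixture_marginal_loglik(m1, dat),
               forward_marginal_loglik(m1$components[[1]], dat),
               tolerance = 1e-12)
  # duplicating a component at half weight changes nothing
  comp <- m1$components[[1]]
  dup <- mixture_model(c(0.5, 0.5), list(comp, comp))
  expect_equal(mixture_marginal_loglik(dup, dat),
               mixture_marginal_loglik(m1, dat), tolerance = 1e-12)
  # two K = 1 components: direct two-term computation per subject
  c1 <- cthmm_model(1, matrix(0, 1, 1), -1, "normal", 0.8)
  c2 <- cthmm_model(1, matrix(0, 1, 1), 2, "normal", 0.8)
  mix <- mixture_model(c(0.4, 0.6), list(c1, c2))
  hand <- 0
  for (n in 1:3) {
    idx <- (dat$offsets[n] + 1):dat$offsets[n + 1]
    o <- dat$outcome[idx]
    hand <- hand + log(0.4 * prod(dnorm(o, -1, 0.8)) +
                       0.6 * prod(dnorm(o, 2, 0.8)))
  }
  expect_equal(mixture_marginal_loglik(mix, dat), hand, tolerance = 1e-10)
})

test_that("component split: weights, centering and the term-by-term oracle", {
  set.seed(53)
  cfg <- move_config(c = 0.6)
  pr <- prior_spec(beta_sd = 1)
  dat <- toy_data(list(c(0, 0.5, 1.2)), list(c(0.3, -0.4, 0.8)))
  for (rep in 1:10) {
    mix <- rand_mix(sample(1:3, 1))
    m <- sample.int(mix$M, 1)
    sp <- propose_component_split(mix, m, cfg, pr)
    expect_equal(sum(sp$model$weights), 1, tolerance = 1e-12)
    expect_equal(sp$model$M, mix$M + 1L)
    # children share Q and pi (centered proposal)
    expect_equal(sp$model$components[[mix$M + 1L]]$Q,
                 mix$components[[m]]$Q)
    expect_equal(sp$model$components[[mix$M + 1L]]$pi,
                 mix$components[[m]]$pi)
    # independent recomputation of the log proposal ratio
    comp <- mix$components[[m]]
    bnew <- sp$model$components[[mix$M + 1L]]$B[1, ]
    w <- sp$w
    logg <- dbeta(w, 2, 2, log = TRUE) +
      sum(dnorm(bnew, comp$B[1, ], cfg$c, log = TRUE))
    n_ord <- rjcthmm:::.comp_pair_orderings(sp$model, m, mix$M + 1L)
    oracle <- log(mix$weights[m]) - logg + log(mix$M) - log(mix$M + 1) +
      log(n_ord)
    expect_equal(sp$log_proposal_ratio, oracle, tolerance = 1e-10)
  }
  # a zero-noise split leaves the marginalized likelihood unchanged
  mix <- rand_mix(2)
  sp0 <- propose_component_split(mix, 1, move_config(c = 1e-300), pr)
  expect_equal(mixture_marginal_loglik(sp0$model, dat),
               mixture_marginal_loglik(mix, dat), tolerance = 1e-10)
})

test_that("component combine: identity, inversion and reciprocity", {
  set.seed(54)
  cfg <- move_config(c = 0.6)
  pr <- prior_spec(beta_sd = 1)
  # combining identical components returns that component exactly
  comp <- rand_mix(1, Ks = 3)$components[[1]]
  mix <- mixture_model(c(0.45, 0.55), list(comp, comp))
  cb <- propose_component_combine(mix, 1, 2, cfg, pr)
  expect_equal(cb$model$components[[1]]$Q, comp$Q, tolerance = 1e-12)
  expect_equal(cb$model$components[[1]]$B, comp$B, tolerance = 1e-12)
  expect_equal(cb$model$components[[1]]$pi, comp$pi, tolerance = 1e-12)
  expect_equal(sum(cb$model$weights), 1, tolerance = 1e-12)
  # combine after a zero-noise split recovers the original mixture
  for (rep in 1:5) {
    mix <- rand_mix(sample(2:3, 1))
    m <- sample.int(mix$M, 1)
    sp <- propose_component_split(mix, m, move_config(c = 1e-300), pr)
    back <- propose_component_combine(sp$model, m, mix$M + 1L, cfg, pr)
    expect_equal(back$model$weights, mix$weights, tolerance = 1e-12)
    for (j in seq_len(mix$M)) {
      expect_equal(back$model$components[[j]]$Q, mix$components[[j]]$Q,
                   tolerance = 1e-12)
      expect_equal(back$model$components[[j]]$B, mix$components[[j]]$B,
                   tolerance = 1e-12)
    }
  }
  # factor reciprocity at matched configurations
  checked <- 0L
  while (checked < 15L) {
    mix <- rand_mix(sample(1:3, 1))
    m <- sample.int(mix$M, 1)
    sp <- propose_component_split(mix, m, cfg, pr)
    if (!sp$admissible) next
    back <- propose_component_combine(sp$model, m, mix$M + 1L, cfg, pr)
    expect_equal(sp$log_proposal_ratio + back$log_proposal_ratio, 0,
                 tolerance = 1e-10)
    checked <- checked + 1L
  }
  # mismatched state counts are refused
  bad <- mixture_model(c(0.5, 0.5),
                       list(rand_mix(1, Ks = 2)$components[[1]],
                            rand_mix(1, Ks = 3)$components[[1]]))
  expect_error(propose_component_combine(bad, 1, 2, cfg, pr), "same number")
})

test_that("cluster sweep keeps the bookkeeping invariants", {
  set.seed(55)
  sc <- builtin_scenario("SIM2-3state-intercept", "normal", 1)
  sim <- simulate_cthmm(sc, n_subjects = 15)
  pr <- prior_spec(beta_sd = 1, Mmax = 5)
  cfg <- move_config(Mmax = 5, Kmax = 5)
  comp0 <- cthmm_model(1, matrix(0, 1, 1), 0, "normal", 1)
  state <- list(mix = mixture_model(1, list(comp0)),
                membership = rep(1L, 15), scales = list(0.3))
  for (it in 1:25) {
    state <- cluster_sweep(state, sim$data, pr, cfg, iter = it)
    occ <- state$occupancy
    expect_equal(sum(occ), 15L)
    expect_true(state$mix$M >= length(unique(state$membership)))
    expect_true(all(state$membership >= 1 &
                    state$membership <= state$mix$M))
    expect_equal(sum(state$mix$weights), 1, tolerance = 1e-10)
    expect_true(state$mix$M <= 5)
    expect_true(all(vapply(state$mix$components, `[[`, 0L, "K") <= 5))
  }
})

test_that("M = 1 with a single component keeps all memberships at 1", {
  set.seed(56)
  sc <- builtin_scenario("SIM2-3state-intercept", "normal", 1)
  sim <- simulate_cthmm(sc, n_subjects = 5)
  pr <- prior_spec(beta_sd = 1, Mmax = 1)
  cfg <- move_config(Mmax = 1, Kmax = 4)
  comp0 <- cthmm_model(1, matrix(0, 1, 1), 0, "normal", 1)
  state <- list(mix = mixture_model(1, list(comp0)),
                membership = rep(1L, 5), scales = list(0.3))
  state <- cluster_sweep(state, sim$data, pr, cfg)
  expect_equal(state$membership, rep(1L, 5))
  expect_equal(state$mix$M, 1L)
})
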