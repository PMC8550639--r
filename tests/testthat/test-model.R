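# Observation model and likelihoods: GLM log-densities, complete-data
# likelihood, forward marginal likelihood.

toy_model3 <- function() {
  cthmm_model(pi = c(0.5, 0.3, 0.2), Q = random_generator(3),
              B = c(-2, 0, 2), family = "normal", sigma = 1)
}

test_that("glm log-densities match direct evaluations", {
  # normal at its mode
  expect_equal(glm_logdensity(1.5, c(1, 0.5), c(1, 1), "normal", sigma = 1),
               -0.5 * log(2 * pi))
  # poisson against a direct factorial evaluation
  expect_equal(glm_logdensity(4, 1, log(4), "poisson"),
               log(4^4 * exp(-4) / factorial(4)))
  expect_error(glm_logdensity(2.5, 1, log(4), "poisson"), "integer")
  expect_error(glm_logdensity(-1, 1, log(4), "poisson"), "integer")
  # additivity over independent observations
  o <- c(0.3, -1, 2); z <- c(1, 1, 1)
  tot <- sum(vapply(o, function(oi)
    glm_logdensity(oi, 1, 0.5, "normal", sigma = 2), numeric(1)))
  expect_equal(tot, sum(dnorm(o, 0.5, 2, log = TRUE)))
})

test_that("complete-data likelihood reduces correctly at K = 1", {
  set.seed(21)
  dat <- toy_data(list(c(0, 1, 2)), list(c(0.5, -0.2, 1)))
  m <- cthmm_model(1, matrix(0, 1, 1), 0.3, "normal", sigma = 1.2)
  p <- latent_path(1L, 0, 2)
  expect_equal(complete_data_loglik(m, list(p), dat),
               sum(dnorm(c(0.5, -0.2, 1), 0.3, 1.2, log = TRUE)))
})

test_that("complete-data likelihood matches the hand-assembly oracle", {
  set.seed(22)
  Q <- generator_matrix(matrix(c(0, 0.8, 1.1, 0), 2, 2, byrow = TRUE))
  m <- cthmm_model(c(0.6, 0.4), Q, matrix(c(-1, 0.5, 2, -0.3), 2, 2),
                   family = "normal", sigma = 0.7)
  Z <- list(matrix(c(1, 1, 1, 0.2, -0.4, 1.1), 3, 2), # subject 1
            matrix(c(1, 1, 1, 0.9, 0.0, -0.5), 3, 2)) # subject 2
  dat <- toy_data(list(c(0, 1, 2.5), c(0, 0.7, 1.9)),
                  list(c(0.1, -0.8, 1.4), c(2.2, -0.1, 0.6)), Z)
  paths <- list(latent_path(c(1L, 2L), c(0, 1.4), 2.5),
                latent_path(c(2L, 1L), c(0, 0.3), 1.9))
  subjects <- list(list(times = c(0, 1, 2.5), outcomes = c(0.1, -0.8, 1.4),
                        Z = Z[[1]]),
                   list(times = c(0, 0.7, 1.9), outcomes = c(2.2, -0.1, 0.6),
                        Z = Z[[2]]))
  expect_equal(complete_data_loglik(m, paths, dat),
               oracle_complete_loglik(m, paths, subjects), tolerance = 1e-10)
  # window mismatch is detected
  short <- list(latent_path(1L, 0, 1.0), paths[[2]])
  expect_error(complete_data_loglik(m, short, dat), "window")
})

test_that("complete-data likelihood is invariant under state relabeling", {
  set.seed(23)
  m <- toy_model3()
  dat <- toy_data(list(c(0, 0.5, 1.3), c(0, 1, 2)),
                  list(c(-2.1, 0.2, 1.8), c(0.1, 2.2, -1.9)))
  paths <- list(latent_path(c(1L, 3L), c(0, 0.6), 1.3),
                latent_path(c(2L, 1L, 2L), c(0, 0.8, 1.5), 2))
  perm <- c(3L, 1L, 2L)  # new label of old state i is match(i, perm)
  m2 <- cthmm_model(m$pi[perm], m$Q[perm, perm], m$B[, perm, drop = FALSE],
                    m$family, m$sigma)
  relab <- function(p) latent_path(match(p$states, perm), p$times, p$horizon)
  expect_equal(complete_data_loglik(m, paths, dat),
               complete_data_loglik(m2, lapply(paths, relab), dat),
               tolerance = 1e-12)
})

test_that("forward likelihood: no-dynamics case and subject additivity", {
  set.seed(24)
  m <- toy_model3()
  dat1 <- toy_data(list(0, 0), list(1.1, -0.4))
  expect_equal(forward_marginal_loglik(m, dat1),
               sum(log(vapply(c(1.1, -0.4), function(o)
                 sum(m$pi * dnorm(o, m$B[1, ], m$sigma)), numeric(1)))),
               tolerance = 1e-12)
  # duplicating a subject doubles its contribution
  dat <- toy_data(list(c(0, 1, 2)), list(c(0.2, -1, 1.5)))
  dd <- toy_data(list(c(0, 1, 2), c(0, 1, 2)),
                 list(c(0.2, -1, 1.5), c(0.2, -1, 1.5)))
  expect_equal(forward_marginal_loglik(m, dd),
               2 * forward_marginal_loglik(m, dat), tolerance = 1e-10)
})

test_that("forward likelihood equals the exhaustive-enumeration oracle", {
  set.seed(25)
  for (family in c("normal", "poisson")) {
    m <- cthmm_model(pi = c(0.5, 0.3, 0.2), Q = random_generator(3),
                     B = if (family == "normal") c(-2, 0, 2) else log(c(1, 3, 6)),
                     family = family,
                     sigma = if (family == "normal") 0.8 else NULL)
    times <- c(0, 0.4, 1.1, 1.9, 3.0)
    o <- if (family == "normal") c(-2.2, 0.3, 1.8, 0.1, -1.7) else
      c(0, 4, 7, 2, 1)
    dat <- toy_data(list(times), list(o))
    expect_equal(forward_marginal_loglik(m, dat),
                 oracle_forward_enum(m, times, o, matrix(1, 5, 1)),
                 tolerance = 1e-8)
  }
})

test_that("forward likelihood does not underflow at T = 60", {
  set.seed(26)
  m <- toy_model3()
  times <- c(0, sort(runif(59, 0, 15)))
  o <- rnorm(60, sample(m$B[1, ], 60, replace = TRUE), 1)
  dat <- toy_data(list(times), list(o))
  ll <- forward_marginal_loglik(m, dat)
  expect_true(is.finite(ll))
})

test_that("forward likelihood is continuous in the coefficients", {
  set.seed(27)
  m <- toy_model3()
  dat <- toy_data(list(c(0, 0.6, 1.4, 2.2)), list(c(-1.9, 0.4, 2.1, 0.0)))
  base <- forward_marginal_loglik(m, dat)
  m2 <- m; m2$B <- m$B + 1e-6
  expect_lt(abs(forward_marginal_loglik(m2, dat) - base), 1e-4)
  expect_gt(abs(forward_marginal_loglik(m2, dat) - base), 0)
})

test_that("importance identity ties the complete and marginal likelihoods", {
  # over prior path draws, the emission likelihood averages to the forward
  # marginal likelihood: E_path[ prod_t f(O_t | X_t) ] = L(o)
  set.seed(28)
  Q <- generator_matrix(matrix(c(0, 1.2, 0.9, 0), 2, 2, byrow = TRUE))
  m <- cthmm_model(c(0.5, 0.5), Q, c(-1, 1), "normal", sigma = 1)
  times <- c(0, 0.5, 1.2)
  o <- c(-0.8, 0.9, 0.2)
  dat <- toy_data(list(times), list(o))
  fwd <- forward_marginal_loglik(m, dat)
  n <- 20000
  w <- numeric(n)
  for (i in seq_len(n)) {
    p <- simulate_ctmc(Q, m$pi, 1.3)
    st <- p$states[findInterval(times, p$times)]
    w[i] <- exp(sum(dnorm(o, m$B[1, st], m$sigma, log = TRUE)) - fwd)
  }
  expect_lt(abs(mean(w) - 1), 3 * sd(w) / sqrt(n))
})

test_that("dataset reader enforces the long-format schema", {
  df <- data.frame(subject = c(1, 1, 2, 2), time = c(0, 1, 0, 2),
                   outcome = c(0.1, 0.5, -1, 2))
  d <- as_cthmm_data(df)
  expect_equal(d$n_subjects, 2L)
  expect_equal(ncol(d$Z), 1L)
  expect_error(as_cthmm_data(df[, c("subject", "time")]), "columns")
  bad <- df; bad$time[1] <- 0.5
  expect_error(as_cthmm_data(bad), "first observation")
  bad2 <- df; bad2$time[2] <- 0
  expect_error(as_cthmm_data(bad2), "strictly increasing")
  df$z1 <- 1; df$z2 <- rnorm(4)
  tmp <- tempfile(fileext = ".csv")
  write_cthmm_data(as_cthmm_data(df), tmp)
  rt <- read_cthmm_data(tmp)
  expect_equal(unname(rt$Z[, 2]), df$z2)
  expect_equal(rt$outcome, df$outcome)
  unlink(tmp)
})
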