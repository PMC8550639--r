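#' Built-in simulation scenarios
#'
#' Returns the data-generating configurations used throughout the package's
#' benchmark studies:
#' \describe{
#'   \item{SIM1-4state}{a four-state model with two time-varying covariates
#'     (one Gaussian, one Bernoulli) besides the intercept.}
#'   \item{SIM2-3state-intercept}{a three-state intercept-only model with
#'     well-separated state means.}
#'   \item{SIM3-4cluster}{a four-cluster mixture whose components have 3, 2,
#'     3 and 4 states and 400/500/450/550 subjects.}
#' }
#' Observation windows run over \code{[0, 15]} time units with a
#' discrete-uniform number of visits between 20 and 60 per subject, the
#' first visit pinned at time 0.
#'
#' @param name scenario name.
#' @param family \code{"normal"} or \code{"poisson"}.
#' @param sigma Gaussian residual standard deviation.
#' @return A scenario configuration list (class \code{cthmm_scenario}).
#' @export
builtin_scenario <- function(name = c("SIM1-4state", "SIM2-3state-intercept",
                                      "SIM3-4cluster"),
                             family = c("normal", "poisson"), sigma = 1) {
  name <- match.arg(name)
  family <- match.arg(family)
  horizon <- 15
  obs_range <- c(20L, 60L)
  if (name == "SIM1-4state") {
    Q <- generator_matrix(matrix(c(
      -3.00, 2.00, 1.00, 0.00,
       1.00, -1.80, 0.75, 0.05,
       0.15, 0.55, -1.05, 0.35,
       0.00, 0.25, 0.40, -0.65), 4, 4, byrow = TRUE))
    B <- matrix(c(
      -1.28, -0.55, -1.05, 0.99,
      -0.88, 1.15, 1.36, 1.73,
       0.70, 0.68, -1.12, -1.20), 3, 4, byrow = TRUE)
    cfg <- list(name = name, clusters = list(list(
      Q = Q, B = B, pi = c(0.35, 0.25, 0.2, 0.2))),
      counts = 1000L,
      covariates = list(list(type = "normal", mean = -1, sd = 1),
                        list(type = "bernoulli", p = 0.6)))
  } else if (name == "SIM2-3state-intercept") {
    Q <- generator_matrix(matrix(c(
      -1.0, 0.6, 0.4,
       0.7, -1.2, 0.5,
       0.3, 0.6, -0.9), 3, 3, byrow = TRUE))
    B <- if (family == "normal") c(-4, 0, 5) else log(c(1.5, 4, 5))
    cfg <- list(name = name, clusters = list(list(
      Q = Q, B = matrix(B, 1), pi = c(0.5, 0.4, 0.1))),
      counts = 1000L, covariates = list())
  } else {
    Q1 <- generator_matrix(matrix(c(
      -2.5, 2.0, 0.5, 0.5, -1.5, 1.0, 0.1, 0.9, -1.0), 3, 3, byrow = TRUE))
    Q2 <- generator_matrix(matrix(c(-1.20, 1.20, 0.25, -0.25), 2, 2,
                                  byrow = TRUE))
    Q3 <- generator_matrix(matrix(c(
      -0.50, 0.49, 0.01, 0.25, -0.30, 0.05, 0.01, 0.10, -0.11), 3, 3,
      byrow = TRUE))
    Q4 <- builtin_scenario("SIM1-4state", family, sigma)$clusters[[1]]$Q
    if (family == "normal") {
      Bs <- list(c(-3, 0, 2), c(-3.5, 3.5), c(-3.8, 1, 4),
                 c(-2, -1.2, 0.7, 1.8))
    } else {
      Bs <- list(log(c(1.5, 4, 5)), log(c(2, 6)), log(c(1.3, 4.2, 7.5)),
                 log(c(0.15, 0.5, 2, 6.2)))
    }
    pis <- list(c(0.5, 0.4, 0.1), c(0.6, 0.4), c(0.45, 0.45, 0.1),
                c(0.35, 0.25, 0.2, 0.2))
    cfg <- list(name = name,
                clusters = lapply(1:4, function(i)
                  list(Q = get(paste0("Q", i)), B = matrix(Bs[[i]], 1),
                       pi = pis[[i]])),
                counts = c(400L, 500L, 450L, 550L), covariates = list())
  }
  cfg$family <- family
  cfg$sigma <- if (family == "normal") sigma else NULL
  cfg$horizon <- horizon
  cfg$obs_range <- obs_range
  structure(cfg, class = "cthmm_scenario")
}

.draw_covariates <- function(laws, T) {
  Z <- matrix(1, T, 1 + length(laws))
  for (j in seq_along(laws)) {
    law <- laws[[j]]
    Z[, j + 1] <- switch(law$type,
      normal = rnorm(T, law$mean, law$sd),
      bernoulli = stats::rbinom(T, 1, law$p),
      stop("unknown covariate law"))
  }
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

#' Simulate longitudinal CTHMM data
#'
#' For each subject: draw a cluster (multi-cluster scenarios), simulate the
#' latent continuous-time path over the horizon, draw the number of visits
#' T uniformly on the configured integer range, place the first visit at
#' time 0 and the remaining T-1 uniformly over the window, draw covariates,
#' and emit outcomes from the GLM at the state occupied at each visit.
#'
#' @param scenario a [builtin_scenario()] or a list with the same fields.
#' @param n_subjects optional override: total subjects, split over clusters
#'   proportionally to the scenario counts.
#' @param counts optional override of the per-cluster subject counts.
#' @return List with \code{data} (a [as_cthmm_data()] object) and
#'   \code{truth} (latent paths, cluster memberships, the scenario).
#' @export
simulate_cthmm <- function(scenario, n_subjects = NULL, counts = NULL) {
  stopifnot(!is.null(scenario$clusters))
  if (is.null(counts)) counts <- scenario$counts
  if (!is.null(n_subjects)) {
    p <- counts / sum(counts)
    counts <- round(n_subjects * p)
    counts[1] <- counts[1] + n_subjects - sum(counts)
  }
  ncl <- length(scenario$clusters)
  stopifnot(length(counts) == ncl)
  rows <- list()
  paths <- list()
  member <- integer(0)
  sid <- 0L
  for (cl in seq_len(ncl)) {
    spec <- scenario$clusters[[cl]]
    for (i in seq_len(counts[cl])) {
      sid <- sid + 1L
      path <- simulate_ctmc(spec$Q, spec$pi, scenario$horizon)
      T <- sample(scenario$obs_range[1]:scenario$obs_range[2], 1L)
      times <- c(0, sort(runif(T - 1L, 0, scenario$horizon)))
      Z <- .draw_covariates(scenario$covariates, T)
      st <- path_state_at(path, times)
      eta <- rowSums(Z * t(spec$B[, st, drop = FALSE]))
      o <- if (scenario$family == "normal") {
        rnorm(T, eta, scenario$sigma)
      } else {
        rpois(T, exp(pmin(eta, 700)))
      }
      df <- data.frame(subject = sid, time = times, outcome = o)
      rows[[sid]] <- cbind(df, as.data.frame(Z))
      paths[[sid]] <- path
      member[sid] <- cl
    }
  }
  data <- as_cthmm_data(do.call(rbind, rows))
  list(data = data,
       truth = list(paths = paths, membership = member, scenario = scenario))
}

#' Write a simulation's ground truth as a JSON sidecar
#'
#' The sidecar stores each subject's true latent path, cluster label, and a
#' compact description of the scenario; it is never read by any fitting
#' routine.
#'
#' @param truth the \code{truth} element of [simulate_cthmm()] output.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    membership = truth$membership,
    paths = lapply(truth$paths, function(p)
      list(states = p$states, times = p$times, horizon = p$horizon)),
    scenario = list(name = truth$scenario$name,
                    family = truth$scenario$family,
                    sigma = truth$scenario$sigma))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
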