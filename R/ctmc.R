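#' Build and validate an infinitesimal generator matrix
#'
#' A generator of a continuous-time Markov chain on \code{1..K} has
#' non-negative off-diagonal jump rates (events per unit time) and rows that
#' sum to zero.  \code{generator_matrix} fills in the diagonal from the
#' off-diagonal rates; \code{validate_generator} checks an existing matrix.
#'
#' @param rates K x K numeric matrix of jump rates; the diagonal is ignored
#'   and recomputed as minus the row sum of the off-diagonal entries.
#' @return A K x K generator matrix.
#' @examples
#' Q <- generator_matrix(matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE))
#' rowSums(Q)
#' @export
generator_matrix <- function(rates) {
  rates <- as.matrix(rates)
  K <- nrow(rates)
  stopifnot(K == ncol(rates), K >= 1)
  diag(rates) <- 0
  if (any(rates < 0)) stop("off-diagonal rates must be non-negative")
  diag(rates) <- -rowSums(rates)
  rates
}

#' @rdname generator_matrix
#' @param Q matrix to validate.
#' @param tol row-sum tolerance.
#' @export
validate_generator <- function(Q, tol = 1e-10) {
  Q <- as.matrix(Q)
  K <- nrow(Q)
  if (K != ncol(Q) || K < 1) stop("generator must be a square matrix, K >= 1")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of a generator must be >= 0")
  if (any(abs(rowSums(Q)) > tol)) stop("generator rows must sum to 0")
  invisible(Q)
}

# strong connectivity of the jump graph (positive off-diagonal rates)
.is_irreducible <- function(Q) {
  K <- nrow(Q)
  if (K == 1L) return(TRUE)
  A <- (Q > 0) & !diag(TRUE, K)
  reach <- function(adj) {
    R <- diag(TRUE, K) | adj
    for (i in seq_len(K)) R <- R | (R %*% R > 0)
    R
  }
  R <- reach(A)
  all(R) && all(t(R))
}

#' Stationary distribution of a CTMC generator
#'
#' Solves \eqn{sQ = 0}, \eqn{\sum_k s_k = 1} by a bordered least-squares
#' solve.  The generator must be irreducible (a single communicating class);
#' otherwise no unique stationary law exists and an error is raised.
#'
#' @param Q generator matrix (see [generator_matrix()]).
#' @return Numeric vector of stationary probabilities.
#' @examples
#' stationary_distribution(generator_matrix(matrix(c(0, 1, 1, 0), 2, 2)))
#' @export
stationary_distribution <- function(Q) {
  validate_generator(Q)
  K <- nrow(Q)
  if (K == 1L) return(1)
  if (!.is_irreducible(Q))
    stop("generator is reducible or has an absorbing state: no unique stationary law")
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  s <- as.vector(qr.coef(qr(A), b))
  s[s < 0 & s > -1e-12] <- 0
  if (any(s < 0) || abs(sum(s) - 1) > 1e-8)
    stop("stationary solve failed (ill-conditioned generator)")
  s / sum(s)
}

#' Interval transition probabilities of a CTMC
#'
#' Computes \eqn{P(dt) = \exp(Q\,dt)} by spectral decomposition when the
#' generator is diagonalizable, falling back to scaling-and-squaring
#' otherwise.  Rows are renormalised to sum to one at rounding-error level.
#'
#' @inheritParams stationary_distribution
#' @param dt non-negative time increment.
#' @return K x K stochastic matrix.
#' @export
transition_probability <- function(Q, dt) {
  validate_generator(Q)
  if (!is.numeric(dt) || length(dt) != 1L || dt < 0) stop("dt must be a single time >= 0")
  if (dt == 0) return(diag(nrow(Q)))
  cpp_trans_prob(Q, dt)
}

#' Latent CTMC trajectory
#'
#' A complete continuous-time path: the visited states and their entry
#' times over a finite horizon.  The first entry time is always 0.
#'
#' @param states integer states in \code{1..K}, consecutive entries distinct.
#' @param times entry times, strictly increasing, first equal to 0, all below
#'   \code{horizon}.
#' @param horizon length of the time window covered by the path.
#' @return An object of class \code{latent_path}.
#' @export
latent_path <- function(states, times, horizon) {
  p <- structure(list(states = as.integer(states), times = as.numeric(times),
                      horizon = as.numeric(horizon)),
                 class = "latent_path")
  validate_latent_path(p)
  p
}

#' @rdname latent_path
#' @param path object to validate.
#' @export
validate_latent_path <- function(path) {
  stopifnot(inherits(path, "latent_path"))
  n <- length(path$states)
  if (n != length(path$times) || n < 1L) stop("states/times length mismatch")
  if (path$times[1] != 0) stop("first entry time must be 0")
  if (n > 1L) {
    if (any(diff(path$times) <= 0)) stop("entry times must be strictly increasing")
    if (any(path$states[-1] == path$states[-n])) stop("consecutive states must differ")
  }
  if (n > 1L && max(path$times) >= path$horizon)
    stop("entry times must lie below the horizon")
  invisible(path)
}

#' @export
print.latent_path <- function(x, ...) {
  cat(sprintf("<latent_path: %d segment(s) on [0, %g]>\n",
              length(x$states), x$horizon))
  invisible(x)
}

# state occupied at each time point in `at`
path_state_at <- function(path, at) {
  path$states[findInterval(at, path$times)]
}

#' Simulate a CTMC path (Gillespie algorithm)
#'
#' Draws the initial state from \code{pi}, then alternates exponential
#' holding times (rate \eqn{-q_{ii}}) and jumps with probabilities
#' proportional to the off-diagonal rates.
#'
#' @inheritParams stationary_distribution
#' @param pi initial distribution on \code{1..K}.
#' @param horizon positive time horizon.
#' @return A [latent_path()].
#' @export
simulate_ctmc <- function(Q, pi, horizon) {
  validate_generator(Q)
  stopifnot(length(pi) == nrow(Q), all(pi >= 0), abs(sum(pi) - 1) < 1e-8,
            horizon > 0)
  r <- cpp_simulate_ctmc(Q, pi, horizon)
  latent_path(r$states + 1L, r$times, horizon)
}

#' Endpoint-conditioned CTMC path sampling
#'
#' Draws an exact realization of the chain on \code{[0, dt]} conditioned on
#' starting in \code{a} and ending in \code{b}.  Direct rejection sampling is
#' used when \code{a == b} and modified rejection sampling (first jump drawn
#' from a truncated exponential) otherwise; after \code{max_attempts}
#' rejections the sampler falls back to uniformization, which is exact for
#' any endpoint pair with positive transition probability.
#'
#' @inheritParams stationary_distribution
#' @param a,b start and end states (1-based).
#' @param dt interval length.
#' @param max_attempts rejection attempts before the uniformization fallback.
#' @return A [latent_path()] with horizon \code{dt}, starting in \code{a} and
#'   ending in \code{b}.
#' @export
sample_conditioned_path <- function(Q, a, b, dt, max_attempts = 30L) {
  validate_generator(Q)
  K <- nrow(Q)
  stopifnot(a >= 1, a <= K, b >= 1, b <= K, dt >= 0)
  if (dt == 0) {
    if (a != b) stop("endpoint pair infeasible over dt = 0")
    return(latent_path(a, 0, 0))
  }
  r <- cpp_sample_conditioned_path(Q, a - 1L, b - 1L, dt, as.integer(max_attempts))
  latent_path(r$states + 1L, r$times, dt)
}
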