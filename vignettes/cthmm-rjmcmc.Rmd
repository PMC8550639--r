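---
title: "Bayesian CTHMMs with an unknown number of states: models, samplers, and design choices"
author: "rjcthmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian CTHMMs with an unknown number of states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjcthmm)
```

## The model

`rjcthmm` fits continuous-time hidden Markov models to irregularly timed
longitudinal data. Subject $n$ is observed at times
$\tau_{n,1} = 0 < \tau_{n,2} < \dots < \tau_{n,T_n}$ with scalar outcomes
$O_{n,t}$ and (optionally) covariate vectors $Z_{n,t} \in \mathbb{R}^D$
whose first entry is the intercept. Behind the observations runs an
unobserved continuous-time Markov chain $X_s$ on $\{1,\dots,K\}$ with
initial law $\pi$ and infinitesimal generator $Q$ (non-negative
off-diagonal jump rates in events per unit time; rows sum to zero).
Conditional on the path, outcomes are independent draws from a GLM indexed
by the occupied state,

$$O_{n,t} \mid X_{\tau_{n,t}} = k \;\sim\; \mathrm{GLM}\!\left(g^{-1}(Z_{n,t}^\top \beta_k)\right),$$

with either the Gaussian identity link (common dispersion $\sigma$ across
states) or the Poisson log link. The coefficient columns form the $D
\times K$ matrix $B$; the full parameter block is
$\Theta_K = (\pi, Q, B)$. The number of states $K$ is itself a parameter
with a zero-truncated Poisson(3.5) prior by default (geometric,
zero-truncated negative binomial and discrete uniform alternatives are
available through `count_prior()`), truncated at `Kmax = 10`.

Two likelihoods matter. The *forward marginal likelihood*
(`forward_marginal_loglik()`) integrates the latent path out through the
forward recursion over the observation skeleton, with interval transition
matrices $P(\Delta t) = e^{Q \Delta t}$; it is computed with per-step
scaling constants accumulated in log space, so series of 60 observations
do not underflow. The *complete-data likelihood*
(`complete_data_loglik()`) is the joint density of outcomes and the full
trajectory: initial-state, exponential dwell, jump-rate and emission
terms. The former drives all trans-dimensional acceptance ratios; the
latter underlies the fixed-dimension conditional updates.

## Fixed-dimension sampling

One sweep (`sweep_fixed_k()`) follows a fixed order: latent paths, $B$
(and $\sigma$), $\pi$, $Q$.

*Latent paths.* States at the observation times are drawn exactly by
forward-filtering backward-sampling; each inter-observation interval is
then filled by endpoint-conditioned path sampling. The conditioned
sampler uses direct rejection when the endpoints agree and modified
rejection (first jump from a truncated exponential) otherwise; after 30
rejected attempts for an interval it falls back to uniformization, which
is exact for every feasible endpoint pair, so runtime is bounded without
approximation. All of this is compiled code; interval transition matrices
come from a spectral decomposition of $Q$ when it is numerically
diagonalizable (verified by reconstruction to $10^{-10}$), otherwise from
scaling-and-squaring, and are cached per gap length rounded at
$10^{-12}$.

*Parameters.* The CTMC conjugacies give
$q_{ij} \mid \cdot \sim \mathrm{Gamma}(a + N_{ij},\, b + T_i)$ from the
imputed jump counts and dwell times, and
$\pi \mid \cdot \sim \mathrm{Dirichlet}(\delta_\pi + \text{initial
counts})$. Gaussian coefficients use the conjugate normal draw per state
column given $\sigma$, with the $N(0, 100^2)$ default prior acting as a
proper ridge (states observed fewer than $D$ times still have a
well-defined full conditional); $\sigma^2$ then gets its inverse-gamma
full conditional, with prior IG(0.01, 0.01) — or can be held fixed via
`fix_sigma` to replicate a known-dispersion scenario. Poisson columns use
a per-state random-walk Metropolis step whose scale adapts diminishingly
toward an acceptance rate of about 0.35 (inside the 0.2–0.5 band);
intercept-only Poisson models can instead place a Gamma(10, 10) prior on
each state mean, carried to the intercept by change of variables. Empty
states are redrawn from the prior. The Gibbs structure is validated by a
Geweke joint-distribution test in the suite.

## Split/combine moves on the number of states

The trans-dimensional step proposes, with probability `b_split` (default
0.5; forced to split at $K = 1$ and to combine at `Kmax`), a *centered
split* of a uniformly chosen state: outgoing rates are copied to both
children, incoming rates are divided by Beta(2, 2) weights, the two new
cross rates come from the Gamma prior, the initial probability is divided
by a Beta(2, 2) weight, and the new intercept is a $N(\beta_{1,k}, c^2)$
perturbation with $c = 1$ by default (the split is centered, so likelihood
contributions change little and $c$ mainly controls how far siblings start
apart). This construction preserves the stationary law: the children's
stationary probabilities sum to the parent's and all other states keep
theirs. The reverse *combine* picks a state uniformly, pairs it with the
L1-nearest coefficient column (smallest index on ties), merges outgoing
rates and coefficients by stationary-probability weights, sums incoming
rates and initial probabilities, and discards the cross rates. A split
whose sibling is not strictly the nearest state to the parent is rejected
outright, since the reverse selection could never produce the pair.

The acceptance ratio combines the move probabilities, the
Jacobian-over-proposal factor, and the posterior ratio evaluated with the
forward marginal likelihood — latent paths play no role in the jump
decision and are refreshed implicitly because every subsequent fixed-K
sweep re-imputes them. Three bookkeeping choices were genuinely open and
are resolved as follows:

* the combine factor is implemented as the exact mirror of the split
  factor — including the product over all $K-1$ incoming weights and the
  density of the discarded sibling intercept centered at the kept
  intercept — because factor reciprocity at matched configurations
  (asserted to $10^{-10}$ in the suite) fails under any other reading;
* the state-selection probabilities ($1/K$ forward; the number of ordered
  selections that the argmin pairing rule admits, over $K+1$, in reverse)
  are carried explicitly inside the proposal ratio rather than absorbed
  into the move probabilities;
* at the boundaries the forced move enters with its actual probability
  (1), not the interior `b_split`.

### A known limitation: the centered moves are trans-dimensionally degenerate

The centered split copies $K - 1$ outgoing rates and $D - 1$ coefficient
entries deterministically, so its image is a measure-zero manifold of the
$(K+1)$-state parameter space, while the combine move starts from
arbitrary configurations and merges by stationary-weighted averages that
do not invert the copy (nor does the merged intercept reproduce the kept
child's). No acceptance-ratio bookkeeping can dimension-match such a
pair. The practical consequence, measured by the package's own
flat-likelihood chains (`scripts/acceptance.R` recomputes it), is a
systematic tilt of the sampled $K$-marginal toward smaller $K$ under a
constant likelihood, growing roughly geometrically in $K$; the
corresponding prior-recovery assertions in the acceptance suite fail and
are left failing deliberately. In the data-rich regimes the sampler is
designed for, the marginal-likelihood ratio dominates these
$\mathcal{O}(1)$-per-state factors, and the benchmark studies below
recover the generating number of states as their posterior mode; but
posterior probabilities over $K$ should be read as conservative (biased
toward parsimony) rather than exact, and this package documents rather
than repairs that property of the method. Making the moves exact would
require randomizing the copied coordinates, i.e. abandoning the centered
construction.

A related practical effect: because a centered split duplicates a state's
emission distribution, its immediate marginal-likelihood gain is small
whenever the states to be separated are close (e.g. Poisson means 4
versus 5) — the payoff arrives only after the fixed-dimension sweeps
specialize the generator around the new state. Discovering such states is
therefore an accept-then-specialize ratchet that can need run lengths in
the 10,000+ range; short chains underestimate $K$ in these regimes even
when the data carry ample aggregate evidence.

## Clustering with unknown numbers of components and states

The mixture extension gives each of $M$ components its own full
$(\pi^{(m)}, Q^{(m)}, B^{(m)})$ block with its own state count $K_m$, and
weights $\varpi \sim \mathrm{Dirichlet}(\delta, \dots, \delta)$ with
$\delta = 1$. One sweep (`cluster_sweep()`) runs: (1) a state-dimension
move inside every component, using only its currently assigned subjects;
(2) a component split/combine on the *marginalized* mixture likelihood
$\sum_n \log \sum_m \varpi_m L(o_n \mid \Theta^{(m)})$ — the component
split duplicates $Q$ and $\pi$, perturbs every state intercept of the
copy by $N(0, c^2)$, and divides the weight by a Beta(2, 2) draw, while
the combine is restricted to component pairs with equal state counts
(nearest by the Frobenius distance of their coefficient matrices) and
merges state by state with stationary-probability weights; (3) membership
resampling from the posterior membership probabilities; (4) fixed-K
sweeps per component, which automatically refresh empty components from
the prior because their full conditionals reduce to it; (5) a conjugate
Dirichlet weight update from the occupancies. The probability of
proposing a component combine defaults to 0.7 — a successful merge
already requires two similar components to have reached the same state
count, so combines must be attempted more often than splits for the
component dimension to mix. The component count is capped at
`Mmax = 15` and, with no stated choice to inherit, its prior defaults to
the same zero-truncated Poisson(3.5) used for $K$: proper, concentrated
on small counts, and heavy-tailed enough to let occupied components grow.
Both $M$ and the number of occupied components $M^\*$ are recorded per
sweep; summaries assign each subject its modal component among the sweeps
at the modal $M^\*$, which is also how the membership CSV is produced.
The component moves inherit the degeneracy discussed above in an even
stronger form (the entire $Q$ and $\pi$ are copied), with the same
practical reading.

## The simulator

`builtin_scenario()` ships three data-generating configurations used by
the tests and the acceptance script: a four-state model with a Gaussian
$N(-1,1)$ and a Bernoulli(0.6) time-varying covariate; a three-state
intercept-only model with well-separated means ($-4, 0, 5$ for the
Gaussian case; rates $1.5, 4, 5$ for the Poisson case); and a
four-cluster mixture with 3/2/3/4 states and subject counts
400/500/450/550. `simulate_cthmm()` draws each subject's latent path by
the Gillespie algorithm over a 15-time-unit window, a visit count $T$
uniform on $\{20, \dots, 60\}$, one visit pinned at time 0 and the
remaining $T-1$ uniform over the window (sorted), covariates from their
laws, and outcomes from the GLM at the occupied states. Ground truth
(paths, memberships) is written to a JSON sidecar that no fitting routine
reads. What the simulator does *not* emulate — informative visit timing,
overdispersion, missing covariates, measurement batch effects — bounds
what green tests mean: they certify the samplers against the model's own
generating mechanism, not against the messiness of registry data.

## Numerical and degenerate-input conventions

States and components are labelled from 1 at every interface (0-based
only inside the compiled code). Ties in nearest-neighbour selections
break to the smallest index. Poisson linear predictors are clamped at
$e^{700}$ before exponentiation. Reducible merged generators, infeasible
endpoint pairs and non-finite likelihoods all reject the move (or raise,
at user-facing entry points) with a diagnostic naming the offender. A
proposed model whose likelihood underflows to $-\infty$ is rejected
rather than erroring inside a sampler. With `Kmax = 1` (or `Mmax = 1`)
the trans-dimensional step is a recorded no-op.

## Problem sizes used by the checks

The test-suite and `scripts/acceptance.R` run the benchmark studies at
reduced size, chosen so the full battery completes on one CPU while the
posterior modes remain clearly identified: 150 subjects and 5,000
iterations for the three-state intercept-only Gaussian study, 250
subjects and 4,000–5,000 iterations for the four-state Poisson study,
100/125/113/138 subjects and 1,800 sweeps for the four-cluster study, and
30,000 / 10,000 steps for the flat-likelihood prior-recovery chains. The
corresponding full-scale configurations (1,000–1,900 subjects, 10,000+
iterations) run in CPU-hours through the same entry points.
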