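# rjcthmm

Bayesian inference for **continuous-time hidden Markov models (CTHMMs)
with an unknown number of hidden states**, and model-based clustering of
longitudinal trajectories with an unknown number of clusters.

The package is aimed at biostatisticians and epidemiologists modelling
irregularly timed longitudinal records — e.g. disease-severity
surveillance from administrative health data, where patients are observed
only when they interact with the system — as noisy readouts of a latent
multi-state process.

## The model and the sampler

Subject *n* is observed at irregular times
τ<sub>n,1</sub> = 0 < … < τ<sub>n,T<sub>n</sub></sub>. A latent
continuous-time Markov chain X<sub>s</sub> on {1, …, K} with initial law
π and generator Q (off-diagonal jump rates q<sub>ij</sub> ≥ 0, rows
summing to zero) drives a generalized-linear observation model

&nbsp;&nbsp;O<sub>n,t</sub> | X<sub>τ</sub> = k ~ GLM(g⁻¹(Zᵀβ<sub>k</sub>)),

with Gaussian-identity (common dispersion σ) or Poisson-log families; the
columns of the D × K matrix **B** are the per-state coefficients. The
parameter block Θ<sub>K</sub> = (π, Q, **B**) lives in spaces of
different dimension as K varies, and K itself carries a zero-truncated
Poisson(3.5) prior.

Inference is by Markov chain Monte Carlo:

* **fixed dimension** — exact latent-path imputation
  (forward-filtering backward-sampling at the observation times, then
  endpoint-conditioned path sampling via rejection with a uniformization
  fallback) followed by conjugate updates of Q and π and
  conjugate/Metropolis updates of **B** (and σ);
* **reversible jump over K** — centered split/combine moves on the
  hidden states: a split copies the parent's outgoing rates, divides
  incoming rates and the initial probability by Beta(2,2) weights, draws
  the two new cross rates from the prior and perturbs only the intercept;
  the stationary law of the chain is preserved by construction. The
  acceptance ratio is evaluated on the forward marginal likelihood;
* **clustering** — a finite mixture whose components are full CTHMMs
  with their own state counts; split/combine moves on the number of
  components run on the marginalized mixture likelihood, with membership
  resampling and per-component sweeps in between.

The numerical core (matrix exponentials, forward recursion, path
samplers) is compiled RcppArmadillo code; see the methods vignette
(`vignettes/cthmm-rjmcmc.Rmd`) for the algorithms, default priors, design
decisions, and known limitations (including a documented parsimony bias
of the centered trans-dimensional moves).

## Worked example

Simulate a three-state intercept-only Gaussian benchmark (state means
−4, 0, 5; σ = 1) and infer the number of states:

```r
library(rjcthmm)
set.seed(1)
scenario <- builtin_scenario("SIM2-3state-intercept", family = "normal", sigma = 1)
sim <- simulate_cthmm(scenario, n_subjects = 60)
fit <- fit_cthmm_rj(sim$data, family = "normal",
                    prior = prior_spec(beta_sd = 1),
                    cfg = move_config(), iterations = 1500, burnin = 500)
k_posterior(fit)
#>   K  prob
#> 1 1 0.000
#> 2 2 0.000
#> 3 3 0.743
#> 4 4 0.256
#> 5 5 0.001
ms <- modal_k_summary(fit)
round(ms$intercepts, 2)
#>       [,1]  [,2] [,3]
#> mean -3.97  0.00 5.03
#> sd    0.04  0.04 0.04
#> lo   -4.05 -0.08 4.96
#> hi   -3.90  0.07 5.10
```

The posterior mode of the number of hidden states is the generating
K = 3 (74% of post burn-in iterations at this small n = 60; the mass
concentrates further as n grows), and the sorted state means conditional
on the modal K recover −4, 0, 5 with tight 95% credible intervals.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/rjcthmm simulate --scenario SIM2-3state-intercept \
        --family normal --n-subjects 200 --seed 1 --out runs/sim
Rscript inst/cli/rjcthmm fit-rj --data runs/sim/data.csv \
        --iters 5000 --seed 2 --out runs/rj
```

Each run writes a JSON-lines trace, posterior tables (CSV), parameter
summaries and a reproducibility manifest.

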