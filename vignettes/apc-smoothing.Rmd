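---
title: "Smoothing and forecasting age-period-cohort surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing and forecasting age-period-cohort surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the identifiable age-period-cohort (APC) model, the two smoothing schools
(penalised regression splines and RW2 intrinsic Gaussian Markov random
fields), forecasting and its uncertainty laws, predictive scoring, the
synthetic-data generator, and the numerical and design decisions behind
each, including the points where reasonable implementations could differ.

## The identifiable APC model

For age group `a = 1, ..., I` and period `p = 1, ..., J`, the cohort index
is `c = M (I - a) + p` with `M` the integer ratio of age-interval width to
period width (`M = 1` for single-year-by-single-year tables; `M = 5` for
five-year age bands by single-year periods).  `K = M (I - 1) + J` cohorts
appear on the grid.  Counts are modelled through a linear predictor on the
log-rate scale,

$$\eta_{ap} = \beta_0 + \beta_1 a + \beta_2 p + f_A(a) + f_P(p) + f_C(c),$$

with `y_ap ~ Poisson(N_ap e^{eta_ap})` by default (`N_ap` the population at
risk, entering as a `log` offset); negative-binomial and gaussian families
are available.  Because `cohort = period − age`, the three linear trends
are exactly confounded and only two slopes are estimable.  Following the
curvature reparameterisation, each `f_T` is constrained to

$$\sum_t f_T(t) = 0, \qquad \sum_t t\, f_T(t) = 0,$$

i.e. orthogonality to its own level and linear trend.  The constrained
curvatures are identifiable; the two retained slopes absorb aspects of the
dropped scale's trend and should not be over-interpreted.  The package
drops the cohort slope by default; `drop_slope = "age"` or `"period"` gives
the same fitted and forecast `eta` (asserted to 1e-6 for splines and within
Monte-Carlo error for the MCMC school in the test suite).

**Constraint mechanics.**  The classical construction uses orthogonal
polynomials; the package instead absorbs the two constraints per component
by a null-space reparameterisation: with constraint matrix
`A = rbind(1, t)` (2 x n) and basis `Z`, coefficients are expressed in the
orthonormal null-space basis of `A Z` obtained from a QR decomposition.
The constrained *function space* is identical to the classical one; only
the internal coordinates differ, so `eta` and the curvature values are
unaffected by this choice.  With saturated components the assembled design
has full column rank `I + J + K − 3` on equal-interval grids.

**Unequal intervals.**  For `M > 1`, `c mod M = p mod M` on the whole grid,
so period-`M` cycles in the cohort curvature alias exactly with cycles in
the period curvature — the "artificial cyclic pattern" of aggregated APC
tables, and the reason a curvature (second-derivative) penalty is essential
there.  Both smoothers resolve it by penalising wiggliness.  Where a unique
*unsmoothed* decomposition of a known surface is needed (defining true
curvatures for parameter-recovery checks), `decompose_eta()` uses the
minimum-norm least-squares solution, which allocates the (negligible, for
smooth surfaces) aliased content symmetrically.

**Index scaling.**  Slope and curvature covariates are centred, unit-spaced
integer indices; age midpoints and calendar years are labels only.  This
keeps design matrices well conditioned and makes the penalties
scale-free.

**Zero counts.**  The half-event correction `log((y + 1/2)/N)` is used only
when *displaying or scoring against* observed log-rates
(`empirical_log_rate()`); model fitting always uses the raw counts.

## School 1: penalised regression splines

Each curvature is `f_T = Z_T γ_T` on a cubic spline basis with equally
spaced knots spanning the index range:

* `"cr"` — the natural-cubic *cardinal* basis: one basis function per knot,
  parameterised by the value at that knot (`g_t(k_s) = 1[s = t]`), built
  from the tridiagonal second-derivative system of natural interpolation;
* `"bs"` — cubic B-splines (sparse, partition of unity);
* `"identity"` — one coefficient per index with a second-difference
  penalty, used for theory checks (it is the bridge to the RW2 school).

The penalty is the exact curvature functional
`S[s,t] = ∫ g_s'' g_t'' dx`, computed in closed form: for `"cr"` as
`D' B^{-1} D` from the natural-spline system, for `"bs"` by exact Simpson
integration of the piecewise-linear second derivatives.  Its null space is
exactly the lines (dimension 2), so after the Holford constraints the
penalised problem is strictly convex.  A `"diff2"` flavour
(second-order coefficient differences, `D'D`) is available; for the
saturated basis it *is* the RW2 structure matrix.

Fitting maximises the penalised log-likelihood
`l(β, γ) − Σ_T λ_T γ_T' S̃_T γ_T` by penalised IRLS (Newton system
`(X'WX + 2P) θ = X'Wz`, log-population offset for count families),
converging when the relative change in penalised deviance falls below 1e-8
(cap 200 iterations, step-halving on non-decrease).  A note on signs: the
penalty enters *subtracted* from the log-likelihood — the objective must
price roughness, not reward it — and the factor 2 above is this package's
convention linking `λ` to the prior precision (below).

**Smoothing-parameter selection.**  `criterion = "gcv"` (default for
gaussian) minimises `n D / (n − EDF)^2`; `criterion = "laplace_reml"`
(default for count families) minimises the negative Laplace-approximate log
marginal likelihood
`−[l_p(θ̂) + ½ Σ_T d_T log λ_T − ½ log|X'WX + 2P|]` (λ-constant terms
dropped).  The optimiser is coordinate descent over `log10 λ_T`: a 13-point
grid on `[−4, 8]` per component, two sweeps, golden-section refinement
around the grid optimum, ties broken toward larger `λ` (the smoother fit).
Three smoothing parameters make a single long 1-D grid impractical; the
coordinate scheme is deterministic, and the test suite asserts that on a
replicate of the simulation design it matches an independent
`mgcv::gam(paraPen=, method="REML")` fit of the identical design to within
5e-3 in `eta` and 1% in standard errors (the selected `λ` differ by
exactly the factor-2 convention).

**Intervals and forecasting.**  The coefficient covariance is the Bayesian
posterior covariance `(X'ŴX + 2P)^{-1}`; intervals are
`η̂ ± z_{0.975} · SE` with the SE from the quadratic form of the prediction
row.  Forecasts evaluate the basis at unobserved periods and the new cohort
diagonals and multiply by the estimated coefficients.  Beyond the boundary
knots both bases continue *linearly*: natural-cubic splines do so by
construction (zero second derivative outside), and the B-spline basis is
extended by its first-order Taylor expansion at the boundary so the two
bases extrapolate on the same principle.  Extrapolation distances are
recorded on the prediction object.

**Negative binomial.**  The dispersion is estimated by profiling the
penalised log-likelihood over `log θ` after smoothing-parameter selection;
it is treated as just another likelihood parameter.

## School 2: RW2 intrinsic GMRF priors

Each curvature field carries the intrinsic second-order random-walk prior

$$\pi(f \mid \tau) \propto \tau^{(n-2)/2} \exp\!\Big(-\tfrac{\tau}{2}
\sum_{t=1}^{n-2} [f(t) - 2f(t+1) + f(t+2)]^2\Big)
= \tau^{(n-2)/2} \exp\!\big(-\tfrac12 f' (\tau R) f\big),$$

with `R = D'D` the banded structure matrix (interior stencil
`(1, −4, 6, −4, 1)`, corners `(1, −2, 1)` and `(−2, 5, −4, 1)`), rank
`n − 2`: constants and linear trends are free, matching exactly what the
spline penalty leaves unpenalised.  The exponent carries the conventional
minus sign and the normalising power of `τ` uses the intrinsic rank.
The rank-2 deficiency is handled by the same two hard constraints per
field (zero sum, zero linear trend); a flat prior on the first two values
is subsumed by treating the field as intrinsic plus constraints.

**PC prior.**  Each precision gets the penalised-complexity prior: an
exponential on the standard deviation `σ = τ^{-1/2}` with rate
`κ = −log(α)/U`, calibrated by the contrast `P(σ > U) = α`.  Defaults
`U = 1, α = 0.01` (a conventional weakly-informative choice); `U ∈ {1, 3, 6}`
is exposed for the simulation roster.  Intercept and slopes get zero-mean
gaussian priors with variance 1e6.

**Sampler.**  Inference is MCMC with a deliberately simple, verifiable
contract:

1. the whole latent gaussian block (slopes and all three fields, dimension
   `3 + I + J' + K'`) is updated jointly by an independence
   Metropolis–Hastings proposal: a gaussian approximation at the
   conditional mode (Newton iterations on the log posterior), sampled via
   its Cholesky factor — exact Gibbs when the family is gaussian, so the
   acceptance ratio is identically 1 there;
2. each `log τ_T` takes a random-walk Metropolis step under the intrinsic
   prior density plus PC prior, step sizes adapted toward ~44% acceptance
   during burn-in only;
3. constraints are enforced by conditioning-by-kriging: each proposal `z`
   is projected to `z − Q^{-1}A'(AQ^{-1}A')^{-1}Az`.  The proposal
   precision is regularised as `Q* = prior + A'A`, a term that is *exactly
   zero* on the constraint set, so the surrogate density equals the
   intrinsic one where the chain lives and no ridge contaminates the `τ`
   updates.

The chain starts at the constrained conditional mode.  This matters: an
independence proposal built from a gaussian approximation cannot escape a
starting state far out in the likelihood's sub-gaussian tail (every
proposal is rejected and, with the curvature stuck at zero, the precision
random walk diverges), whereas started in the high-mass region the latent
acceptance rate is typically 0.9–1.0.  Default budget: 20,000 iterations,
5,000 burn-in, thinning 5; identical seed and configuration reproduce the
samples bit for bit.

**Summaries and forecasting.**  Point predictions are per-cell posterior
medians; intervals are the 2.5%/97.5% posterior quantiles (at least 100
retained samples are required).  For a horizon `t`, the period field is
extended to `J + t` and the cohort field to `M(I−1) + J + t`; the added
cells are unobserved pseudo-data contributing nothing to the likelihood, so
their `eta` posterior *is* the forecast.  Conditional on the fitted field,
a pure RW2 forecast has mean `(1+t) f_n − t f_{n-1}` (linear continuation)
and variance `t(t+1)(2t+1)/(6τ)` — cubic growth, versus the roughly linear
growth of the spline SE.  This is the entire story of the forecasting
comparison: both schools extrapolate the *point* forecast the same way, but
they price future-curvature uncertainty differently.

## The bridge between the schools

Writing the penalised likelihood as `L × exp(−λ γ' S γ)` shows the penalty
as an improper gaussian prior with precision `2λS` (rank `T − 2`).  With
the saturated basis and difference penalty, `S = R`, and the penalised fit
equals the RW2 posterior mode at fixed precision when `λ = τ/2` — the
factor follows from this package's conventions (`−λγ'Sγ` in the objective,
`−τ/2 f'Rf` in the prior) and is pinned by a 1e-8 equivalence test.  The
practical difference is how much smoothing is done and how its uncertainty
is carried: cross-validation-style point selection of `λ` (splines) versus
a posterior over `τ` (RW2), which propagates smoothing uncertainty into
intervals.

## Predictive scoring

Scores compare predictions with truth on the linear-predictor (log-rate)
scale, separately for estimation and forecasting cells: MAE and MSE
(averaged per cell over replicates, then over cells), mean interval width,
empirical coverage, and the 95% interval score

$$\mathrm{IS}_\alpha = (u - l) + \tfrac{2}{\alpha}(l - \eta)\,1[\eta < l]
+ \tfrac{2}{\alpha}(\eta - u)\,1[\eta > u], \qquad \alpha = 0.05,$$

aggregated by *mean* over cells (means keep windows of different sizes
comparable).  IS equals the width when the truth is covered and penalises
misses linearly in the violation; the central-quantile interval of the true
predictive distribution minimises its expectation.  For simulated data the
"truth" is the noiseless generator surface; for observed data it is the
empirical log-rate, with or without the half-event correction (both
supported; the report records which).

## The synthetic-data generator

`sim_config()` emulates a rare-cause national mortality surface:
single-year ages 10–84 by periods 2000–2020, a fixed 750,000 population at
risk per single-year cell, Poisson counts (negative binomial optional),
aggregation of ages into five-year bands summing counts and exposure
(summing exposure preserves expected counts), modelling at band midpoints
12.5, ..., 82.5 (`M = 5`), an estimation window of 2000–2017 and a
three-year forecast window.  The default intercept (−11.3) puts aggregated
cells near 46 events on average, the scale of a rare cause of death in a
national population.  The truth surface handed to scoring is the *exact*
aggregated log mean rate `log(Σ N e^η / Σ N)`, not the single-year `η`.

True effects are linear trends plus smooth curvature shapes, each supplied
as an injectable function with a scale, projected onto the constraint
space: a gaussian bump in age (amplitude 0.9 — mortality risk concentrating
in mid-life), a 14-year sinusoid in period (amplitude 0.25), and a 35-index
cosine in cohort (amplitude 0.3).  The cyclic shapes are deliberately
pronounced: the package's own design choice is that the forecast window
must *bend away* from the linear continuation of the estimation window by
more than a few tenths on the log scale, because that is the regime in
which interval calibration — not point accuracy — separates the two
schools; with near-linear truth every method covers trivially and the
comparison degenerates.  Period swings of ±25% in a rare-cause death rate
over a decade are large but within the range seen in, e.g., alcohol-related
mortality.  What the generator does *not* emulate: population dynamics
(exposure is constant), secular breaks or shocks (effects are smooth and
periodic), reporting artefacts, and age-heaping.  Passing tests on this
generator therefore demonstrate correctness of the machinery and the
calibration contrast under smooth-but-curved truth, not robustness to
structural breaks.

## Study orchestration

`run_simulation_study()` runs the full comparison: per replicate, generate
single-year counts, aggregate, fit every roster model
(`study_models()`: spline bases × knot counts, RW2 × `U`) on the
estimation window, forecast the holdout, score both windows against the
generator truth.  Replicate `r` uses seed `global_seed × 10^4 + r`; a model
failure is recorded and skipped, and more than 20% failures aborts the
study.  Outputs are per-cell scores, per-replicate-window means (the
boxplot quantities; `autoplot()` draws them), and grand means.
`run_real_data()` is the same workflow for an observed table: the spline is
fitted to the estimation-window rows only, the RW2 model to the full grid
with held-out counts as unobserved pseudo-data — the two protocols are
verified equivalent to deleting the rows outright.

The test suite exercises a scaled study — 20 replicates, one spline and one
RW2 specification, an MCMC budget of 1,600 iterations — and the
parameter-recovery check runs at ten times the default population; both are
the package's chosen problem sizes for routine verification, with the
defaults (`N = 100`, full roster, 20,000 iterations) intended for real use.

## Numerical choices, in one place

* PIRLS: relative penalised-deviance tolerance 1e-8, 200-iteration cap,
  step-halving; initial `eta` from `log(y + 1/2) − log N`.
* Selection: 13-point `log10 λ` grid on `[−4, 8]`, two coordinate sweeps,
  golden refinement (tolerance 0.02 in `log10 λ`), ties toward larger `λ`.
* Knots: defaults 10 (age), 10 (period), 12 (cohort), equally spaced,
  clamped to the index length; at least 4 for a cubic basis, and never more
  knots than distinct values.
* MCMC: Newton mode-finding to 1e-10 step tolerance (cap 50), `log τ` step
  sizes adapted every 50 burn-in iterations toward 0.3–0.5 acceptance,
  `exp` arguments capped at 300 to keep stray proposals finite, chain
  started at the constrained mode.
* Constraint algebra: QR-based null spaces; kriging projection under
  `Q* = prior + A'A`; constraint violations of retained samples are below
  1e-8 of the field scale by construction.
* Degenerate inputs rejected with messages: non-integer width ratios,
  fewer than two ages/periods, non-positive exposure, negative or
  fractional counts (unless the family is gaussian), ragged aggregation
  bands, horizons below 1, fields shorter than 3 for second differences.

## Known limitations

* Thin-plate regression splines, tensor-product smooths and
  quasi-likelihoods are out of scope; the two implemented bases bracket the
  practical choices and results are insensitive to the basis.
* The Bayesian engine is MCMC, not a deterministic nested-Laplace
  approximation; posterior summaries agree with closed forms in the
  gaussian case, but sample-path equality with other software is not a
  goal, and runtimes grow with the latent dimension
  (`3 + I + J' + K'`, dense Cholesky per iteration).
* Age-interval width must be an integer multiple of the period width, and
  aggregation bands must tile the age range exactly; Lexis triangles are
  not handled.
* Forecast uncertainty under the spline school reflects coefficient
  uncertainty only; that its intervals are too narrow under curved truth is
  a finding, not a bug, but users who need calibrated long-horizon
  intervals should prefer the RW2 school.
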