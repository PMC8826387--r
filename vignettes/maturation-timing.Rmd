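---
title: "Torpor metrics and maturation-timing models in heterostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torpor metrics and maturation-timing models in heterostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterostat)
```

## The problem

Small heterothermic mammals can trade reproduction against survival by
entering torpor: a controlled drop of metabolic rate and body temperature
that saves energy but slows temperature-dependent processes such as
spermatogenesis. In a captive two-arm experiment, male bats are held below
their thermoneutral zone at two ambient temperatures (10 °C and 25 °C)
while skin temperature is logged every 10 minutes, body mass is recorded
daily, and sexual maturation is staged on an ordinal 0–4 scale (0 = no
visible testicular growth, 2 = maximal testes, 4 = regressed testes with
filled epididymides) roughly every 10 days. `heterostat` provides the two
bespoke pieces of the analysis — torpor/thermoregulation metrics from the
logger series, and a Bayesian hierarchical model of the *days* on which
bats cross maturation-class boundaries — plus a seeded generator of
complete synthetic studies so the whole pipeline can be tested without
field data.

Days are numbered from capture (day 0); the temperature treatment starts on
day 10, after acclimation.

## Torpor and thermoregulation metrics

Each bat gets an individual torpor-onset threshold from the allometric
linear rule

$$T_{\mathrm{sk\text{-}onset}} = 0.041\,M_b + 0.04\,T_a + 31.083
\quad[^\circ\mathrm{C}],$$

where $M_b$ is body mass (g) and $T_a$ ambient temperature (°C). The
right-hand side already carries the one-standard-error buffer of the
underlying regression and is used directly as the cutoff. By default the
bat's mean mass over its records enters the rule, giving one stable
threshold per individual; a config flag switches to day-specific masses.
A *torpor bout* is a maximal run of at least three consecutive included
readings strictly below the threshold. Excluded readings (evening
handling, feeding, flight — configured as daily clock windows) and logger
re-deployments break runs: there is no information about the bat while it
is handled, so a bout interrupted by handling counts as two. Bout duration
is `n_readings × 10 min`, so an isolated reading contributes exactly one
sampling interval and gaps cannot inflate durations.

Daily thermoregulation effort is summarised by
$\Delta T = \operatorname{mean}(T_{sk} - T_a)$ over the day's included
readings. $\Delta T$ is signed and never clamped — logger noise can push
$T_{sk}$ below $T_a$, and clamping would bias the energetic
interpretation of the mean. Days are delimited at midnight and bouts are
credited to the day containing their start.

## The maturation-timing model

The ordinal stage sequence is modelled directly on the day axis. For bat
$i$ examined on day $t$, the latent maturation time is $t + u_i$ with a
per-bat shift $u_i \sim N(0, \sigma_u^2)$ (days). The first transition
(class 0→1) is fixed at day 10 — the treatment onset, by which about half
the animals have passed it — and carries no effects, anchoring the scale.
Every later transition $k$ has an effective day

$$T_{k,ij} = \tau_k + d_k\,\mathbb{1}[\text{treat}_i = T_{10}] +
\gamma^{M}_{g,k}\,m_{ij} + \gamma^{\Delta}_{g,k}\,\delta_{ij},$$

with $\tau_k$ the baseline (warm-arm) transition day, $d_k$ the cold-arm
delay in days, and $\gamma$ the per-treatment effects of centred body mass
$m_{ij}$ and centred $\Delta T$ $\delta_{ij}$ recorded on the examination
day, in days per centred unit. Observation follows a cumulative
ordered-probit rule,

$$P(y_{ij} \ge k) = \Phi\!\left(\frac{t_{ij} + u_i - T_{k,ij}}
{\sigma_\varepsilon}\right),$$

with cell probabilities by differencing. This parameterisation makes every
reported quantity — transition days, delays, effects — a direct model
parameter in days. The probit (Gaussian) link matches the Gaussian
random-intercept structure; a logit link is available as a config option.
$\sigma_\varepsilon$ is the latent observation noise, distinct from the
between-bat $\sigma_u$.

Covariates missing on an examination day (no logger coverage, no mass
record) are *not* interpolated: they are sampled inside the model from a
Gaussian with estimated mean and standard deviation, with all observed
values of the covariate informing those hyper-parameters. On a dataset
with nothing missing the imputation block is provably inert (it shares no
term with the rest of the posterior), which the tests verify.

### Priors and parameterisation

Baseline ordering $\tau_2 < \tau_3 < \tau_4$ is enforced by sampling
positive increments from day 10, each with a half-Normal(50 d) prior.
Treatment delays get Normal(0, 50² d²). Covariate effects get a
deliberately tighter Normal(0, 15² (d/unit)²): centred covariates span a
few units here, and a two-sigma effect under a 50 d/unit prior would shift
thresholds by more than the study length. That matters for calibration:
when a transition sits near the edge of the observation window (few
crossings observed in one arm), an over-wide effect prior acts as extra
threshold dispersion, inflates the implied crossing probability, and
biases the estimated delay upward — a prior-sensitivity effect the
recovery simulations below make visible. $\sigma_u$ and
$\sigma_\varepsilon$ get half-Normal(20 d); imputation hyper-means
Normal(0, 10²) and hyper-sds half-Normal(10) on the centred covariate
scale. These are weakly informative at the scale of a two-month study; a
`prior_rescale` flag doubles or halves all of them at once for sensitivity
checks. Dividing the day axis by 365 is retained as an option
(`use_year_scale`) — it rescales data, fixed threshold and day-unit priors
jointly and is mathematically the same model, which a test asserts by
comparing chains — but the default works in days directly.

### Sampling and diagnostics

Inference is by adaptive Metropolis-within-Gibbs: single-site Gaussian
random-walk updates, with per-parameter step sizes adapted during burn-in
only (target acceptance 0.44), so retained draws come from a fixed kernel.
Random-effect and imputed-covariate updates touch only the observations
they enter. Because single-site sweeps mix the scale of a hierarchy
slowly, each iteration adds one joint rescaling move on
$(\sigma_u, u_1, \dots, u_n)$ — an ancillarity–sufficiency interweaving
step whose acceptance ratio reduces to the likelihood and the $\sigma_u$
prior, the random-effect densities cancelling exactly against the
transform Jacobian. This keeps $\hat R$ for $\sigma_u$ well below 1.1 at
the chain lengths used in testing. Chains start from random draws from the priors (variance
components floored away from zero so no chain starts in a degenerate
likelihood), each chain on a seed derived from the root seed, making runs
bit-reproducible on one platform. The study-scale defaults mirror the
field analysis — 3 chains × 50 000 iterations, 20 000 burn-in, thinning
by 3 — while the test suite uses 5 000-iteration chains with a
2 000-iteration burn-in, which converge comfortably at these data sizes.

Convergence is assessed with the Gelman–Rubin potential scale reduction
factor (split-chain variant), converged when $\hat R < 1.1$; a fit with
any larger $\hat R$ is flagged and warned about, never suppressed. A
parameter is reported "significant" when its central 95% credible
interval excludes 0. The transition into the top class is reported only
when at least two bats were observed there; with fewer, its posterior
reflects the prior rather than the data.

### Numerical choices

Covariate-shifted thresholds can momentarily lose their ordering for
extreme effect draws; the resulting negative cell probabilities are
floored at $10^{-12}$ and counted, and the count is reported on the fit
object. Quantiles use linear interpolation (type 7). The minimum chain
length accepted by `gelman_rubin()` is 4, the shortest length for which
split-half variances exist. Duplicate timestamps, non-positive masses,
unknown treatment tokens and classes outside the configured range are
rejected at read time; data in which every examination shows the same
class stop the fit with an explicit "unidentifiable" error.

## The synthetic-study generator

`sim_config()` encodes the study conditions: 36 bats captured mid-June,
capture mass uniform in 9.4–12.8 g and forearm length in 34.0–46.9 mm (the
field cohort's ranges), treatments assigned by splitting consecutive
body-condition (forearm/mass) pairs at random, housing groups of three
within arm, a 10-day acclimation followed by 52 treatment days, and
examinations every 10 days. Mass trajectories are piecewise-linear
treatment-specific trends (warm: dip then slow recovery; cold: brief rise
then steady decline) plus Gaussian noise. Cold-arm skin-temperature traces
sit just above ambient with one evening arousal per day; warm-arm traces
fluctuate in the 24.2–30.6 °C daytime band with a couple of brief
normothermic excursions per day. Traces get Gaussian noise, 0.5 °C
quantization, and a floor at ambient. The arousal shapes are qualitative
mimics — free knobs, not estimates — because the model under test only
consumes examination-day covariate values.

Maturation observations are drawn from the transition-time model itself
(the generative twin of the likelihood): the default true parameters are
the study-scale estimates ($\tau$ = 39.37, 62.81 days; delays 33.48,
37.12 days; the reported mass and $\Delta T$ effects), with
$\sigma_u = \sigma_\varepsilon = 5$ days — plausible between-bat and
staging noise at a 10-day examination cadence, chosen once; the class 3→4
transition, not estimable in the source study, gets a nominal late
baseline (day 85) and zero effects. By default classes are made
non-decreasing over a bat's exams (spermatogenesis stages are
sequential); the flag is off in likelihood-consistency and
parameter-recovery tests, because the running maximum is a
post-processing step outside the fitted likelihood. All stages draw from
named substreams of one root seed, so adding a generator stage never
perturbs the others.

What passing tests show — and what they do not: the generator reproduces
the *structure* of the field data (sampling grids, quantization,
exclusions, missingness, ordinal cadence, treatment imbalance of
covariates), so green tests demonstrate that the pipeline computes its
quantities correctly and recovers known parameters from data of this
shape and size. They do not validate the physiological realism of the
trace shapes, ad libitum feeding effects, group composition effects, or
the field estimates themselves.

## Verification strategy and problem sizes

The oracle hierarchy, smallest to largest (sizes chosen to keep the suite
quick at one CPU):

- torpor detection against a brute-force maximal-run scan on 1 000 random
  quantized series with random exclusions and deployment splits;
- the likelihood against longhand ordered-probit arithmetic on a two-exam
  toy (to 1e-10), and the compiled log-posterior against a pure-R replica
  on random parameter vectors (to 1e-9);
- the sampler against dense grid integration of a reduced model (two
  bats, one free transition, fixed variance components) — posterior mean
  within two Monte-Carlo standard errors;
- parameter recovery on 20 simulated 30-bat cohorts (exams every 10 days
  to day 60, true $\tau$ = 40/62, delays 30/35, $\sigma_u =
  \sigma_\varepsilon = 5$, covariate effects truly zero): the fit matching
  the generative process (no covariate terms) must give absolute bias of
  $\hat\tau_2$ within 3 days, 95%-CI coverage at least 0.85 per
  parameter and all $\hat R < 1.1$; the same 20 datasets are then refit
  with the full effect structure, where significance flags may fire for at
  most 10% of the truly-null effects. The cold-arm transition sits at day
  70 with observations ending at day 60, so the effects-free fit is also
  the honest measure of timing calibration — the full fit's delay
  posterior absorbs effect-prior dispersion there (see the prior note
  above);
- end-to-end bit-reproducibility of simulate → thermo → covariates → fit
  under a fixed seed.

## Limitations

- The model treats examination days as exact and covariates as measured
  without error; only missingness is modelled.
- Per-threshold covariate effects are estimated independently; there is no
  pooling across transitions, so late transitions observed in few animals
  have prior-dominated effects (hence the top-transition reporting gate).
- The sampler is exact but not gradient-based; for much larger cohorts a
  reparameterised HMC implementation would mix faster.
- $\Delta T$ is a proxy for thermoregulatory energy expenditure, valid
  below the thermoneutral zone; the package does not estimate metabolic
  rate.
- Smooth time-course analyses of mass and $\Delta T$ (e.g. GAMMs) are out
  of scope; standard smoothing packages cover them.
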