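# heterostat

Energy allocation in heterothermic mammals: when ambient temperature
drops, a small bat can defend its body temperature (expensive) or let it
fall into torpor (cheap, but spermatogenesis stalls in cold testes).
`heterostat` is an R package for captive two-arm experiments that probe
this trade-off — male bats held at 10 °C vs 25 °C with skin-temperature
loggers, daily weighing, and ordinal staging of sexual maturation
(classes 0–4, from no visible testicular growth through maximal testes to
regressed testes with filled epididymides) roughly every 10 days. It is
aimed at ecophysiologists who have logger exports, mass sheets and
staging records and want torpor metrics plus maturation-timing estimates
with honest uncertainty.

The package provides:

- **Torpor metrics.** Individual torpor-onset thresholds
  `T_sk-onset = 0.041 M_b + 0.04 T_a + 31.083` (°C; mass in g, ambient
  in °C), detection of torpor bouts (≥ 3 consecutive 10-min readings
  below threshold, runs broken by handling exclusions and logger gaps),
  and daily summaries including the thermoregulation-effort proxy
  `ΔT = mean(T_sk − T_a)`.
- **A hierarchical Bayesian model of maturation timing.** A cumulative
  ordered-probit model on the day axis: the day bat *i* (random shift
  `u_i ~ N(0, σ_u²)`) crosses transition *k* is
  `T_k = τ_k + d_k·1[T10] + γ_M[g,k]·mass_c + γ_Δ[g,k]·ΔT_c`,
  with the first transition fixed at day 10 and
  `P(class ≥ k) = Φ((t + u_i − T_k)/σ_ε)`. Baseline transition days
  `τ_k`, cold-arm delays `d_k` and covariate effects are all in days.
  Missing exam-day covariates are imputed from an estimated Gaussian
  inside the model. Sampling is multi-chain adaptive
  Metropolis-within-Gibbs (compiled core) with a joint `(σ_u, u)`
  rescaling move, split-chain Gelman–Rubin diagnostics (converged when
  `R̂ < 1.1`), and a significance rule of 95% credible intervals
  excluding zero.
- **A seeded synthetic-study generator** (cohort, logger traces, mass
  trajectories, ordinal exams drawn from the transition-time model) so
  the full pipeline is testable end to end without field data.

## Worked example

Simulate a 12-bat study, run the thermoregulation pipeline, and fit the
maturation model:

```r
library(heterostat)

cfg   <- sim_config(n_bats = 12, seed = 42)
sc    <- study_config(day0 = cfg$day0_date)
study <- simulate_study(cfg, file.path(tempdir(), "demo"))

ex  <- build_exam_table(study$obs, study$masses, study$dailies, study$bats)
fit <- fit_maturation(ex, maturation_spec(), chains = 3,
                      iter = 15000, burnin = 5000, thin = 3, seed = 42)
fit
summary(fit)
```

which prints (abridged):

```
Hierarchical maturation-timing fit
  bats: 12  transitions: 4 (first fixed at day 10)
  chains: 3 x 15000 iterations (burn-in 5000, thin 3)
  max Rhat: 1.033 (converged)

 parameter   mean    sd    q2.5    q50 q97.5 rhat significant
    tau[2] 33.092 10.75  13.735 32.641  55.1 1.00        TRUE
    tau[3] 67.203 14.32  40.529 66.982  96.4 1.03        TRUE
  delay[2] 62.457 29.74   9.644 60.089 127.3 1.00        TRUE
  delay[3]  0.747 50.64 -99.540  0.831  98.6 1.00       FALSE
   sigma_u  4.803  2.64   0.418  4.642  10.6 1.00        TRUE
 sigma_eps  6.687  1.90   3.520  6.476  11.0 1.00        TRUE
```

`tau[2]` is the posterior day (since capture) on which a baseline-arm
(25 °C) bat of average mass and ΔT moves from maturation class 1 to 2;
`delay[2]` is the extra days a 10 °C bat needs for the same transition.
On 12 bats the intervals are wide; `delay[3]` is prior-dominated (no
cold-arm bat reaches class 3 inside the study window) and its interval
honestly spans zero. Note that `delay[2]` exceeds the generator's
treatment-only delay: in this design the cold arm also differs
systematically in ΔT, which truly affects transitions, so part of the
covariate pathway is absorbed into the arm contrast — the same
confounding a real experiment of this shape faces.

Thermoregulation output from the same run:

```r
aggregate(cbind(delta_t_c, n_torpor_events) ~ treatment,
          merge(study$dailies, study$bats[c("bat_id", "treatment")]), mean)
#>   treatment delta_t_c n_torpor_events
#> 1       T10 0.6999474        1.016129
#> 2       T25 3.0495072        2.741935
```

Cold-housed bats sit in torpor just above ambient (low ΔT, one long bout
per day); warm-housed bats cycle in and out (more, shorter bouts, higher
ΔT).

## Scope

Smooth time-course modelling of body mass and ΔT (GAMM-style analyses)
is deliberately out of scope — standard smoothing packages handle it; the
package's own contributions are the torpor metrics and the
transition-time model. See `vignettes/maturation-timing.Rmd` for the
model's assumptions, priors, numerical choices and limitations.
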