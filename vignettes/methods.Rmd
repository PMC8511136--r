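---
title: "Modeling intermittent radiotherapy for recurrent high-grade glioma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intermittent radiotherapy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtsim)
```

## The problem

Recurrent high-grade glioma has no curative option; re-irradiation is
delivered with palliative intent. The standard debulking course —
hypofractionated stereotactic radiotherapy (HFSRT), five ≥6 Gy fractions
on consecutive days — eradicates radiosensitive clones up front, which by
competitive release can accelerate the expansion of resistant ones, and
spends the entire radiation budget in one week. The alternative studied
here is *intermittent* radiotherapy (iRT): the same single fractions
delivered every ~6 weeks, synchronized with response imaging, optionally
followed by a three-fraction boost on consecutive days when progression is
detected. `irtsim` implements the growth–response model, its calibration
to longitudinal volume measurements, counterfactual schedule simulation,
and the outcome statistics used to compare arms.

## Model and assumptions

The observed volume is `V = V_l + V_d`. Viable tumor grows exponentially
at a rate `lambda` shared across patients and is killed by systemic
therapy (bevacizumab + pembrolizumab) at a rate `gamma(t)` that decays
exponentially with resistance evolution:

$$\frac{dV_l}{dt} = \lambda V_l - \gamma(t) V_l,\qquad
  \frac{d\gamma}{dt} = -\varepsilon\gamma,\qquad
  \gamma(0)=\gamma_0=\lambda .$$

Each radiation fraction instantaneously transfers a proportion
$1-S$ of viable volume into a dying compartment that resolves at rate
$\lambda$ (death on attempted division):

$$V_l(t^+) = S\,V_l(t^-),\qquad
  V_d(t^+) = V_d(t^-) + (1-S)\,V_l(t^-),\qquad
  \frac{dV_d}{dt} = -\lambda V_d .$$

Key assumptions, stated plainly:

* **Exponential growth, no carrying capacity.** Over the few-hundred-day
  horizons of interest the growth curve is treated as exponential; for
  large regrown tumors this overestimates growth, making schedule
  comparisons conservative ("worst case") for iRT.
* **`S` is a parameter, not a dose response.** All fractions, including
  boosts, use the same surviving fraction; no linear–quadratic dose
  dependence, no radiation-induced immune stimulation.
* **The drug clock is global.** `gamma(t)` decays from the single
  treatment start `t0` (first fraction and drug start coincide) and is
  never reset by fractions, boosts, or progression.
* **Drug kill acts only on viable tumor**; the dying compartment follows
  its own exponential resolution.
* **The pre-treatment tumor is entirely viable** (`V_d(t0) = 0`); the
  model is silent about earlier therapy, and this is the simplest
  consistent initial condition.

Between fractions the system is solved in closed form, so trajectories
are propagated piecewise-analytically and evaluated exactly at arbitrary
times (`simulate_trajectory()`, `trajectory_volume()`). The
`epsilon -> 0` limit is handled by a dedicated analytic branch below
`1e-12`/day rather than by division.

## Parameters

| parameter | unit | meaning | bounds / default |
|---|---|---|---|
| `lambda` | day⁻¹ | growth rate, shared | [0.017, 0.14] (doubling 5–40 d); population value 0.065 |
| `S` | – | surviving fraction per fraction | [0, 1] |
| `epsilon` | day⁻¹ | resistance-evolution rate | [0, 0.1]; optimizer floor 1e−6 |
| `gamma0` | day⁻¹ | initial drug kill rate | tied to `lambda` |
| `V0` | cm³ | pre-treatment volume | measured baseline × [0.7, 1.3] |

The `gamma0 = lambda` tie and the shared `lambda` are the
parameter-sharing configuration selected by AIC (`aic_compare()`
reproduces that comparison on synthetic cohorts); they also mean a
freshly treated tumor starts at zero net growth and regrows as resistance
accumulates — the observed clinical pattern.

## Calibration choices

* **Objective.** Sum of relative squared differences
  `((sim − meas)/max(meas, 0.5 cm³))²`. The 0.5 cm³ denominator floor is
  this package's choice for zero/near-zero measured volumes (the source
  analysis is silent); it matches the bootstrap's small-volume
  uncertainty scale.
* **Optimizer.** The original analysis used a single SQP run with 1e−9
  step/optimality tolerances. Here: L-BFGS-B on a unit cube
  (`S` linear, `epsilon` log₁₀-scaled, `V0` relative to baseline) with a
  10-start Latin-hypercube multistart guarding the nonconvex objective,
  `factr = 10` and finite-difference step 1e−6. On noise-free synthetic
  data this recovers generative parameters to ~1e−9 relative error.
* **Epsilon search floor.** `epsilon` is searched in [1e−6, 0.1]/day on a
  log scale although its bound is [0, 0.1]: below 1e−6/day the drug term
  is observationally indistinguishable from `epsilon = 0` over study
  horizons (γ decays by <0.1% in 300 days). Fits of truly
  resistance-free patients land on the floor, which downstream code
  treats like any other small rate.
* **Grid search.** `lambda` is chosen on a doubling-time grid of 5–40
  days by minimizing mean + median + min + max of per-patient RMSEs. The
  methods text of the source analysis defines this four-term score while
  a figure caption mentions a three-term variant; the four-term text
  definition is normative here, with `score_terms` as a config option.
* **Bootstrap.** Measurement noise N(1, 0.2²) multiplicative at ≥2 cm³,
  additive N(0, 0.5² cm³) below (the stated "0.5 cm³ uncertainty" has no
  distributional form; additive Gaussian matches its
  volume-independence), negatives clamped to zero; 50 replicates refit
  only `(S, epsilon)` with `V0` and `lambda` held at the point fit. All
  measured points, including the baseline, are perturbed, but `V0` is not
  refit. Ties against the incumbent point estimate are resolved in the
  incumbent's favor in exact arithmetic, so a zero-noise bootstrap
  reproduces the point fit bit for bit — a contract the tests assert.

## Schedule simulation choices

* Assessments occur exactly every 42 days from `t0` (baseline first);
  assessment precedes any same-day fraction, mirroring image-then-treat.
  Simulated assessments carry no jitter — cadence jitter belongs to the
  measurement generator only.
* Progression: assessed volume strictly exceeding 1.2 × the running
  minimum of all previous assessed volumes (baseline included, current
  excluded).
* At most one boost per simulation (the published figures describe a
  single boost event); `max_boosts` raises this. Boost fractions land on
  the progression day and the two following days; a fraction already
  scheduled on the progression day is delivered first, and the remaining
  planned fractions stay on schedule so arms remain comparable. Boost
  fractions are additional to the n planned fractions.
* The drug term keeps decaying smoothly past simulated progression
  (systemic therapy continued until progression in the trial, and the
  simulated boost arms continue past it).
* Time-to-cutoff `tau` is the *first* time `V(t)` reaches the cutoff
  (the patient's last recorded volume; fallback 1.2 × `V0`), located by a
  0.05-day scan plus root bracketing on the analytic segments to ±0.01
  day, censored at the 1500-day horizon (past the longest reported
  progression time). A cutoff at or below baseline yields `tau = 0` —
  see the generator caveats below.

## Outcome statistics

Kaplan–Meier and logrank are delegated to the `survival` package,
rank-sum to `wilcox.test` (exact enumeration for combined n ≤ 10 without
ties — the trial-scale regime — otherwise normal approximation with tie
correction), Pearson to `cor.test`; the test suite checks each against
hand-computed oracles (manual product-limit, hypergeometric tally, exact
enumeration). The two-sample rank-sum test is used for group contrasts:
the compared patient sets are unpaired, whatever the original figure
captions call the test. gEUD is `(Σ vᵢ Dᵢᵃ)^{1/a}` with `a = −10`;
the uniform-dose case short-circuits to the dose itself so the exactness
contract holds to the bit. Response groups: Group 1 HFSRT best, Group 2
boost compensates inferior iRT, Group 3 boost extends non-inferior iRT,
Group 4 iRT alone best; comparisons use a 1-day tolerance and exact
three-way ties fall into Group 4 (the "non-inferior without needing the
boost" reading). No multiple-testing correction is applied anywhere.

## What the synthetic cohort does and does not emulate

`draw_cohort()` generates the world the calibration assumes: shared
`lambda = 0.065`/day, `S` uniform on [0.07, 0.90] and `epsilon`
log-uniform on [0.05, 202]×10⁻⁴/day (the fitted extremes; the fitted
values span four decades, hence log-uniform), `V0` uniform on [1, 60]
cm³, gEUD uniform on [31.3, 37.5] Gy, one baseline measurement at day 0
plus 4–10 post-treatment points, inter-measurement gaps N(42, 10²) days
truncated at 7 (the trial's raw cadence sd of 38 days reflects protocol
irregularities that would break assessment semantics), and the stated
20%/0.5 cm³ noise model. The ground truth is simulated under the
delivered five-fraction daily course; `treated = FALSE` gives untreated
series for growth-rate tests.

Not emulated: imaging and contouring themselves, spatial geometry,
informative dropout, and the trial's *selection for observed regrowth*.
That last gap matters for interpretation: a strongly responding synthetic
patient can end observation with their last (cutoff) volume below
baseline, which the first-crossing rule scores as `tau = 0` in every arm
— a degenerate tie (Group 4) that the published cohort, selected for
regrowth, never contains. Green round-trip tests therefore establish
parameter recovery and pipeline correctness under the model's own
assumptions, not fidelity to any real cohort.

## Numerical notes and limitations

* Trajectories are exact closed forms; the only numerics are the
  crossing search (±0.01 day) and the optimizer. The RK4 oracle
  comparison in the tests holds to <1e−8 relative error over random
  in-bounds parameter draws.
* `epsilon` is weakly identified when small: over a ~300-day window a
  rate of 1e−4/day bends log-volume by only ~0.2. Point fits for such
  patients are honest but wide — visible in the bootstrap ensembles —
  and median (not per-patient) recovery is what the acceptance criterion
  asserts.
* AIC model comparison uses the least-squares form
  `n log(RSS/n) + 2k` with pooled absolute residuals (the source
  analysis does not state its likelihood). On noise-free data RSS
  collapses toward zero and the log term degenerates, so the
  sharing-recovery demonstration requires a noisy cohort.
* Fraction-count and boost monotonicity of `tau` hold exactly in the
  model (extra fractions only remove viable volume); the tests allow a
  0.02-day slack for the crossing search, nothing more.
* With no drug effect and `S < 1`, the number of fractions delivered by
  any time `t` is non-increasing in the inter-fraction interval, so
  volume is pointwise non-decreasing and `tau` non-increasing in the
  interval: prolonging intervals beyond the imaging cadence can only
  erode the benefit. The tests assert that forced direction.
* The pipeline's config files are JSON; stage seeds derive
  deterministically from the master seed, and every output file records
  the seed and a config fingerprint, making `synth → fit → simulate →
  compare` bit-reproducible.
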