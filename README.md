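# irtsim

Simulation and calibration toolkit for comparing **hypofractionated
stereotactic radiotherapy (HFSRT)** against **intermittent radiotherapy
(iRT)** schedules in recurrent high-grade glioma, where re-irradiation is
combined with bevacizumab and pembrolizumab. The package asks the planning
question: for a patient whose longitudinal tumor volumes have been
observed under the standard 5 × daily-fraction course, would spreading the
same fractions out at ~6-week intervals — optionally with a 3-fraction
boost at progression — have prolonged the time to tumor regrowth?

It is aimed at mathematical-oncology and radiotherapy-modeling groups who
want a tested, scriptable implementation of this class of
tumor-growth-inhibition analysis, including a synthetic virtual-patient
generator so that every stage runs without access to trial data.

## Model

Observed volume is the sum of a viable and a dying compartment,
V(t) = V_l(t) + V_d(t), with

- dV_l/dt = λ V_l − γ(t) V_l  — exponential growth at shared rate λ
  (day⁻¹) minus a drug-attributable kill rate,
- dγ/dt = −ε γ, γ(0) = γ₀ = λ — the drug effect decays at the
  patient-specific resistance-evolution rate ε,
- at each radiation fraction: V_l → S·V_l, V_d → V_d + (1−S)·V_l — a
  proportion 1−S of viable tumor becomes dying tissue (surviving fraction
  S is a free parameter, not a dose function),
- dV_d/dt = −λ V_d — dying tissue resolves at the growth rate
  (death on attempted division).

Between fractions the system has the closed form
V_l(t) = V_l(t₀)·exp{λ(t−t₀) + (γ₀/ε)(e^(−ε(t−t₀)) − 1)}, so trajectories
are propagated piecewise-analytically (no ODE solver in the hot path; an
RK4 oracle cross-checks it in the tests).

Calibration fixes λ by a population grid search over doubling times of
5–40 days (score: mean + median + min + max of per-patient RMSEs) and fits
(S, ε, V₀) per patient by constrained multistart minimization of the sum
of relative squared differences, with bootstrap uncertainty from 20%
multiplicative contouring noise (0.5 cm³ absolute below 2 cm³). Outcomes
are scored as the time τ for V(t) to reach the patient's cutoff volume,
compared across arms by Kaplan–Meier/logrank, rank-sum contrasts, Pearson
correlations, a four-group response classification, and gEUD dosimetry
summaries (Lyman exponent −10).

## Worked example

```r
library(irtsim)

# one virtual patient: volumes measured under the delivered HFSRT course
pat <- draw_patient(cohort_spec(seed = 1), seed = 31, id = "P31")
m <- data.frame(day = pat$measurements$day,
                volume = pat$measurements$volume_cm3)

fit <- fit_patient(m, lambda_growth = 0.065)
fit
#> Model fit: S = 0.522, epsilon = 0.0125 /day, V0 = 20.89 cm^3 (lambda = 0.065)
#>   RMSE 59.7 cm^3 over 6 points; converged: TRUE

# counterfactual arms under identical fitted parameters
arms <- compare_protocols(fit$params, list(
  HFSRT       = make_hfsrt(),                # 5 daily fractions, days 0-4
  iRT         = make_irt(),                  # 5 fractions, every 42 days
  `iRT+boost` = make_irt(boost = TRUE)))     # + 3 daily fractions at progression

taus <- sapply(names(arms), function(a)
  time_to_cutoff(arms[[a]], pat$cutoff_volume)$time)
round(taus, 1)
#>     HFSRT       iRT iRT+boost
#>     177.5     166.1     210.4

classify_group(taus["HFSRT"], taus["iRT"], taus["iRT+boost"])
#> [1] 2
```

This patient's drug response decays quickly (ε ≈ 0.013/day), so plain iRT
reaches the cutoff volume (their last recorded 810.8 cm³) 11 days sooner
than HFSRT — but the progression-triggered boost more than compensates
(Group 2: boost restores non-inferiority). Patients with slow resistance
evolution (small ε) instead benefit from iRT outright (Group 4).

The full pipeline (generate → fit → simulate → compare) also runs from the
command line:

```sh
Rscript -e 'irtsim::irtsim_main()' synth    --seed 1 --out run/
Rscript -e 'irtsim::irtsim_main()' fit      --out run/ --lambda 0.065
Rscript -e 'irtsim::irtsim_main()' simulate --out run/
Rscript -e 'irtsim::irtsim_main()' compare  --out run/
```

producing `measurements.csv`, `truth.csv`, `fits.csv`, `bootstrap.csv`,
`survival.csv`, `km.csv`, `groups.csv` and `report.json`, every file
stamped with the seed and a config fingerprint.

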