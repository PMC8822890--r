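# hiitsim

Can a training model prescribe a workout that is physically impossible?
`hiitsim` answers that question for the two models most used to prescribe and
analyse high-intensity interval training (HIIT) in cycling:

* the **Skiba W'-balance model** — a finite anaerobic reserve W′ (J) drains at
  rate `P − CP` above the critical power CP and its deficit refills as
  `W′ − (W′ − W′bal)·exp((P − CP)·Δt/W′)` below it; exhaustion occurs when
  `W′bal = 0`;
* the **Coggan-Modified model** — a session of duration `T` leads to
  exhaustion when its Normalized Power (fourth root of the mean fourth power
  of 30-s rolling-average power) equals `Pmax(T)`, the athlete's best mean
  power over `T`; equivalently, when the session's Training Stress Score
  `(NP/FTP)²·T/3600` reaches the maximum attainable over `T`.

For any interval session layout (repetitions × work duration × rest duration,
rest at 50% of 5-min power), each criterion pins down a unique work-interval
power `P*` that would drive the athlete to exhaustion on the final repetition.
For the Skiba model it has the closed form

    P* = CP + W′·(1 − λ) / (t_work·(1 − λⁿ)),   λ = exp((P_rest − CP)·t_rest / W′)

and for the Coggan-Modified model it is the root of `NP(P) = Pmax(T)`, found
by bisection. A session is **impossible** when `P*` strictly exceeds the
athlete's personal-best power over the work-interval duration: the model's
exhaustion condition would require beating a lifetime best on every
repetition. Sweeping a 6198-session grid for three bundled cyclist archetypes
(Time-Trialist, All-Rounder, Sprinter) quantifies how often each model breaks.

The package is tidyverse-native: every stage takes and returns tibbles,
results chain with the pipe, fitted critical-power models support
`tidy()`/`glance()`, and result types have `autoplot()` methods.

## Worked example

```r
library(hiitsim)

tt <- bundled_profiles("time_trialist")
tt
#> <athlete_profile> time_trialist: 17 nodes over [1, 14400] s
#>   CP 304 W | W' 21.5 kJ | MAP 382 W | FTP 281 W | mass 70 kg

# 2 x 15 s work with 5 min recovery at 191 W: what power exhausts W'?
plan <- session_plan(n_reps = 2, work_s = 15, rest_s = 300, rest_power = 191)
solve_power_skiba(plan, cp = tt$cp, wprime = tt$wprime)
#> [1] 1491.865

pmax_power(tt, 15)
#> [1] 777
```

The Skiba model asks this athlete to hold 1492 W twice, yet their best-ever
15-s effort is 777 W — the prescription is impossible (ratio 192% of the
personal best). Classifying the whole grid:

```r
records <- run_grid(bundled_profiles())   # 2 models x 3 profiles x 6198 sessions
report_fractions(records)
#> Model: coggan_modified
#>   all_rounder       1.42 % impossible (n = 6198)
#>   sprinter          0.63 % impossible (n = 6198)
#>   time_trialist     3.89 % impossible (n = 6198)
#>   min/max across profiles: 0.63 / 3.89 %
#> Model: skiba
#>   all_rounder      10.92 % impossible (n = 6198)
#>   sprinter          4.03 % impossible (n = 6198)
#>   time_trialist    21.12 % impossible (n = 6198)
#>   min/max across profiles: 4.03 / 21.12 %
```

Impossible sessions concentrate in short work intervals (under 3 min for the
Skiba model) at severe/extreme intensities with long recoveries, hit the most
enduring profile hardest, and are always more frequent under the Skiba model
than under the Coggan-Modified one. `summarize_sessions()` +
`autoplot()` break the fractions down by prescribed %MAP, interval duration,
total work time, or rest duration; `simulate_wbal()` exports and plots W′
trajectories; `generate_profile()` / `endurance_sweep()` rerun everything on
parametric synthetic profiles. A thin CLI over the same functions lives at
`inst/cli/hiitsim.R` (`grid`, `report`, `profiles`, `wbal`, `np`).

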