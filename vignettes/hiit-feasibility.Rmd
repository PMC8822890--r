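---
title: "Modelling the feasibility of HIIT prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the feasibility of HIIT prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiitsim)
library(dplyr)
```

## The question

Two models dominate the prescription and analysis of high-intensity interval
training (HIIT) in cycling. The **Skiba W'-balance model** tracks a finite
anaerobic work reserve, W' (joules), that drains whenever power exceeds the
critical power CP and refills exponentially below it; exhaustion is declared
when the balance reaches zero. The **Coggan model** summarises any ride by its
Normalized Power (NP), a fourth-power-weighted rolling average; a natural
exhaustion criterion — the *Coggan-Modified* model — is that a maximal session
of duration `T` attains the largest Training Stress Score available over `T`,
which algebraically reduces to `NP = Pmax(T)`, the athlete's best mean power
over the session duration.

Both criteria pin down, for a given interval session layout, the unique
work-interval power that would drive the athlete to exhaustion on the last
repetition. `hiitsim` solves that power over a large grid of session layouts
and asks a simple feasibility question: does the solved power exceed the
athlete's *personal-best* power over the work-interval duration? If it does on
every repetition, the prescription is physically impossible — the model's
exhaustion condition cannot be reached — which exposes a logical limit of the
model in the severe and extreme intensity domains.

## The models in detail

### W' balance

Above CP the reserve drains linearly in the power surplus; over a
constant-power step of length `dt`,

    wbal <- wbal - (P - CP) * dt

Below CP the *deficit* `W' - wbal` decays exponentially, at a rate set by the
power shortfall and by the size of the full reserve:

    wbal <- W' - (W' - wbal) * exp((P - CP) * dt / W')

Both updates are exact for piecewise-constant power, so a session of `n` work
bouts (duration `t_w`, power `P`) separated by `n - 1` rest bouts (duration
`t_r`, power `P_r < CP`) composes in closed form. Each rest multiplies the
accumulated deficit by `lambda = exp((P_r - CP) * t_r / W')`, each work bout
adds `(P - CP) * t_w`, and requiring the final deficit to equal `W'` gives the
exhaustion power

    P* = CP + W' * (1 - lambda) / (t_w * (1 - lambda^n))

`solve_power_skiba()` implements this closed form; a bisection search over the
1-Hz simulation (`simulate_wbal()`) is retained as an independent route and
the two agree to well under 0.01 W on randomised plans. For `n = 1` the
formula collapses to the continuous critical-power relation
`P* = CP + W'/t_w`, and as `t_r -> 0` it tends to `CP + W'/(n * t_w)`.

### Normalized Power

`normalized_power()` follows the four-step algorithm exactly: 30-s rolling
means of the 1-Hz trace, fourth powers, their mean, fourth root. Windows are
the `T - 29` *fully contained* 30-sample windows, stepped one sample at a
time; no partial or padded windows enter the mean. The original description
does not state the window alignment, so this choice is one of the places where
an exact numeric reproduction of published percentages cannot be guaranteed.
A session needs at least 30 s of data, which is why the grid filter below
drops shorter sessions.

One consequence of full containment worth knowing: NP is the quartic mean of
the window means and therefore never falls below *their* arithmetic mean, but
it can fall below the full-series mean on arbitrary traces, because the first
and last 29 samples enter fewer windows. For constant traces `NP = P`
identically, which makes the `n = 1` session solve to exactly `Pmax` and
classify as possible.

`solve_power_coggan()` finds the work power at which the session NP equals
`Pmax(T)` by bisection — NP is continuous and strictly increasing in the work
power, so the root is unique. Internally the solver evaluates NP from the
tabulated number of work samples per window, which depends only on the session
layout; this is algebraically identical to recomputing the rolling means at
every iteration (the tests assert bitwise agreement) but costs a few dozen
operations per iteration instead of a pass over the trace. The solver returns
the sub-target edge of the final bracket so the solved power never overshoots
the target: an exactly attainable target classifies as possible rather than
impossible-by-rounding.

## Athlete profiles and interpolation

A profile is a table of best mean power over 17 durations from 1 s to 4 h,
plus CP and W'. Between nodes, `pmax_power()` interpolates **linearly in power
against log duration**. Power-duration curves are locally near log-linear, and
this interpolant is monotone and reproduces the nodes exactly; but it replaces
whatever continuous model generated the nodes, and it is the dominant source
of numeric divergence when comparing grid percentages with analyses built on a
continuous curve. No extrapolation is allowed outside the tabulated range.

The three bundled archetypes (Time-Trialist, All-Rounder, Sprinter) span the
endurance/anaerobic trade-off: equal or similar aerobic ceilings, but the
Time-Trialist retains the most power at long durations and the least at short
ones. Their CP and W' constants are carried as canonical inputs rather than
re-derived: the conventional 2–15-min work-duration fit
(`estimate_cp_wprime()`) applied to the five printed nodes in that window
yields ≈318 W / 16 kJ for the Time-Trialist, not its canonical 304 W /
21.5 kJ, because the constants were originally fitted on a dense continuous
curve rather than on five tabulated points. The fit function remains the right
tool for data you own; the discrepancy is a property of sparse tabulation.

MAP is simplified to the best 5-min mechanical power, and the rest intensity
of every simulated session defaults to 50% of it — a realistic active-recovery
intensity. We verified the alternative reading (deriving MAP from a metabolic
W/kg figure at 20% gross efficiency) and it moves the headline fractions far
from the published ones, so the mechanical convention is clearly the one in
use.

## The session grid

`generate_plans()` enumerates work durations 15–300 s and rest durations
15–300 s (15-s steps) with 2–20 repetitions, keeping sessions whose total
duration `n*t_w + (n-1)*t_r` — work first, work last, no trailing rest — lies
in the inclusive range [30 s, 90 min]. That convention and inclusivity were
fixed by brute-force enumeration: they are the unique combination that yields
the expected 6198 plans. Rest-interval handling above CP never arises here
(half of MAP is below CP for every bundled profile); the solvers raise a
model-domain error if asked.

A session is **impossible** when the solved work power *strictly* exceeds the
athlete's best power over the work-interval duration — "surpass" is read as
strictly greater, which also keeps the `n = 1` Coggan identity case possible
at a ratio of exactly 100%.

```{r grid, eval = FALSE}
records <- run_grid(bundled_profiles())   # 2 models x 3 profiles x 6198 plans
report_fractions(records)
```

On the full grid this prints impossible-session fractions of roughly 4.0–21.1%
across profiles for the Skiba model and 0.6–3.9% for the Coggan-Modified
model, ordered Time-Trialist > All-Rounder > Sprinter within each model and
Skiba > Coggan-Modified within each profile; every Skiba-impossible session
uses work intervals under 3 minutes. (These numbers are recomputed by the
test suite and by `scripts/acceptance.R`; the full two-model run takes about a
minute on one core.) `summarize_sessions()` breaks the same records down by
prescribed intensity (5 %MAP bins by default — the binning is configurable
since no canonical width exists), interval duration, total work time, or rest
duration, and `autoplot()` draws the resulting curves.

## Synthetic profiles

`generate_profile()` builds a profile from three interpretable parameters:
MAP (anchored as the 5-min power), an endurance slope in %MAP per log10-decade
of duration beyond 5 min, and an anaerobic reserve shaping a hyperbolic branch
below 5 min. The two branches meet continuously at 300 s and the curve is
strictly decreasing; CP and W' are then estimated from the generated nodes by
the 2–15-min fit, mirroring how they would be obtained from real data. The
generator is deliberately a *surrogate*: it reproduces the qualitative shape
of athlete power-duration curves, not any physiological model, and it is
deterministic given its parameters (property tests draw the parameters from
stated uniform ranges under a fixed seed). Passing tests on synthetic profiles
therefore demonstrate the pipeline's internal consistency, not agreement with
physiological measurements.

`endurance_sweep()` regenerates the profile over a vector of endurance slopes
and reruns the grid: the impossible fraction grows monotonically as the slope
flattens (more endurance), reproducing the profile effect as a property. The
packaged check runs the sweep on a thinned grid (45-s work/rest steps, 772
plans) purely to keep it brisk; the effect is the same on the full grid.

## Numerical choices

* Skiba solver: closed form (exact); verification bisection uses a
  `[CP + 1e-6, 10^4]` W bracket and a 1e-3 W tolerance.
* Coggan solver: bisection bracket `[rest power, 10 * Pmax(t_w)]` (doubled if
  ever insufficient), 200-iteration cap, 1e-3 W tolerance on `|NP - target|`;
  returns the sub-target bracket edge.
* Exhaustion inside a step is located by linear interpolation (depletion is
  linear in time); crossings within 1e-6 J of zero count as exhaustion to
  absorb round-off at exact-depletion boundaries.
* The W' trajectory is reported un-clamped up to the exhaustion time and stops
  there.
* TSS uses the unscaled definition (1.0 for an hour at threshold); a
  `scale_100` switch provides the conventional display scale only.
* Solver failures inside a grid run annotate the affected record
  (`solver_error` column) instead of aborting the run.

## Limitations

* Grid percentages inherit the interpolation choice; with profiles tabulated
  at 17 nodes the headline fractions reproduce published continuous-curve
  analyses to within about 1–2 percentage points, not exactly.
* The feasibility criterion only catches sessions that break the athlete's
  absolute best over the work duration; sessions that are merely implausible
  (for instance, repeated efforts each just under the personal best with
  minimal rest) are not identified.
* Only earlier-iteration W'-balance variants, metabolic/mechanical power
  conversion, and chronic training-load metrics (CTL/ATL, TRIMP, sRPE) are out
  of scope, as are validations against physiological data.
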