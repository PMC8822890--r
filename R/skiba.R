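#' W'-balance depletion over a constant supra-critical effort
#'
#' Above critical power, the remaining anaerobic work capacity is drained at a
#' rate equal to the power surplus over CP, so over a constant-power step the
#' balance falls linearly: `wbal - (power - cp) * dt`. The result may be
#' negative, signalling that exhaustion occurred inside the step; callers
#' detect the zero crossing.
#'
#' @param wbal Current W' balance (J).
#' @param power Power output (W), must be `>= cp`.
#' @param cp Critical power (W).
#' @param dt Step duration (s), positive.
#' @return Updated W' balance (J), possibly negative.
#' @export
wbal_deplete <- function(wbal, power, cp, dt) {
  if (any(power < cp)) {
    abort("Depletion requires power >= cp; route sub-CP segments to wbal_recover().",
          class = "hiitsim_contract_error")
  }
  if (any(dt <= 0)) abort("`dt` must be positive.", class = "hiitsim_contract_error")
  wbal - (power - cp) * dt
}

#' W'-balance reconstitution over a constant sub-critical effort
#'
#' Below critical power the deficit `wprime - wbal` decays exponentially at a
#' rate proportional to the depth of the deficit and to the power shortfall
#' below CP:
#' `wprime - (wprime - wbal) * exp((power - cp) * dt / wprime)`.
#' The balance approaches, and never exceeds, the full reserve `wprime`.
#'
#' @param wbal Current W' balance (J), in `[0, wprime]`.
#' @param wprime Full anaerobic reserve W' (J).
#' @param power Power output (W), must be `< cp`.
#' @param cp Critical power (W).
#' @param dt Step duration (s), non-negative.
#' @return Updated W' balance (J).
#' @export
wbal_recover <- function(wbal, wprime, power, cp, dt) {
  if (any(power >= cp)) {
    abort("Recovery requires power < cp; route supra-CP segments to wbal_deplete().",
          class = "hiitsim_contract_error")
  }
  wprime - (wprime - wbal) * exp((power - cp) * dt / wprime)
}

#' Simulate the W'-balance trajectory of a session
#'
#' Steps the W' balance through the plan's alternating work/rest segments at a
#' fixed time resolution, depleting above CP and reconstituting below it. The
#' trajectory starts at the full reserve and stops at exhaustion: the first
#' time the balance reaches zero, located by linear interpolation within the
#' crossing step. The balance is not clamped; the crossing time is reported
#' instead.
#'
#' @param plan A [session_plan()] with `work_power` set above `cp`.
#' @param cp Critical power (W).
#' @param wprime Anaerobic reserve W' (J).
#' @param dt Step size (s), default 1 (1 Hz). Updates are exact for
#'   piecewise-constant power at any `dt`, so `dt` only sets the sampling of
#'   the returned trajectory.
#' @return A tibble of class `wbal_trajectory` with columns `time_s` and
#'   `wbal_j`, and attributes `exhaustion_time` (s, or `NA` if never reached),
#'   `cp` and `wprime`.
#' @export
#' @examples
#' plan <- session_plan(3, 60, 120, rest_power = 150, work_power = 400)
#' traj <- simulate_wbal(plan, cp = 300, wprime = 20000)
#' attr(traj, "exhaustion_time")
simulate_wbal <- function(plan, cp, wprime, dt = 1) {
  stopifnot(inherits(plan, "session_plan"), nrow(plan) == 1)
  if (is.na(plan$work_power)) {
    abort("`plan$work_power` must be set; solve it first or supply it.",
          class = "hiitsim_validation_error")
  }
  if (plan$n_reps > 1 && plan$rest_power >= cp) {
    abort("Recovery is undefined at or above CP: rest_power must be < cp.",
          class = "hiitsim_model_domain_error")
  }
  if (plan$work_power <= cp) {
    abort("`work_power` must exceed cp for a supra-threshold work interval.",
          class = "hiitsim_model_domain_error")
  }
  segs <- plan_segments(plan)
  times <- 0
  wbals <- wprime
  t0 <- 0
  w <- wprime
  exhaustion <- NA_real_
  for (i in seq_len(nrow(segs))) {
    len <- segs$duration_s[i]
    p <- segs$power_w[i]
    steps <- seq(dt, len, by = dt)
    if (length(steps) == 0 || steps[length(steps)] < len) steps <- c(steps, len)
    if (segs$is_work[i]) {
      wk <- wbal_deplete(w, p, cp, steps)
    } else {
      wk <- wbal_recover(w, wprime, p, cp, steps)
    }
    cross <- which(wk <= 1e-6)  # J; absorbs round-off at exact-depletion boundaries
    if (length(cross) > 0) {
      j <- cross[1]
      w_prev <- if (j == 1) w else wk[j - 1]
      t_prev <- if (j == 1) 0 else steps[j - 1]
      # linear interpolation inside the crossing step (depletion is linear)
      frac <- if (wk[j] == w_prev) 0 else w_prev / (w_prev - wk[j])
      exhaustion <- t0 + t_prev + frac * (steps[j] - t_prev)
      keep <- seq_len(j - 1)
      times <- c(times, t0 + steps[keep], exhaustion)
      wbals <- c(wbals, wk[keep], 0)
      break
    }
    times <- c(times, t0 + steps)
    wbals <- c(wbals, wk)
    w <- wk[length(wk)]
    t0 <- t0 + len
  }
  structure(
    tibble::tibble(time_s = times, wbal_j = wbals),
    class = c("wbal_trajectory", class(tibble::tibble())),
    exhaustion_time = exhaustion,
    cp = cp,
    wprime = wprime
  )
}

#' Plot a W'-balance trajectory
#'
#' @param object A `wbal_trajectory` from [simulate_wbal()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wbal_trajectory
#' @export
autoplot.wbal_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$wbal_j / 1000)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "W' balance (kJ)") +
    ggplot2::theme_minimal()
}

#' Work intensity driving W' to zero at the end of the last work interval
#'
#' Solves, in closed form, the constant work-interval power that leaves the W'
#' balance exactly depleted at the end of the final work bout of the plan.
#' With a constant rest power below CP, each rest interval shrinks the
#' accumulated deficit by the factor
#' `lambda = exp((rest_power - cp) * rest_s / wprime)`, and each work bout adds
#' `(P - cp) * work_s` to it; summing the geometric series and setting the
#' final deficit to `wprime` gives
#' `P* = cp + wprime * (1 - lambda) / (work_s * (1 - lambda^n))`.
#' For `n_reps = 1` this reduces to the continuous critical-power relation
#' `P* = cp + wprime / work_s`.
#'
#' @param plan A [session_plan()]; its `work_power` is ignored.
#' @param cp Critical power (W).
#' @param wprime Anaerobic reserve W' (J).
#' @param method `"closed_form"` (default) or `"bisection"`, which searches the
#'   same root by bisection over the final balance of [simulate_wbal()]; the
#'   two agree to well under 0.01 W and the bisection path serves as an
#'   independent check.
#' @param tol Bisection tolerance on power (W); ignored for the closed form.
#' @return The exhaustion work power P* (W).
#' @export
#' @examples
#' plan <- session_plan(4, 60, 120, rest_power = 150)
#' solve_power_skiba(plan, cp = 300, wprime = 20000)
solve_power_skiba <- function(plan, cp, wprime,
                              method = c("closed_form", "bisection"),
                              tol = 1e-3) {
  stopifnot(inherits(plan, "session_plan"), nrow(plan) == 1)
  method <- match.arg(method)
  if (plan$n_reps > 1 && plan$rest_power >= cp) {
    abort("Recovery is undefined at or above CP: rest_power must be < cp.",
          class = "hiitsim_model_domain_error")
  }
  n <- plan$n_reps
  if (method == "closed_form") {
    if (n == 1) return(cp + wprime / plan$work_s)
    lambda <- exp((plan$rest_power - cp) * plan$rest_s / wprime)
    return(cp + wprime * (1 - lambda) / (plan$work_s * (1 - lambda^n)))
  }
  # bisection on the final W' balance of the simulated trajectory
  final_wbal <- function(p) {
    pl <- plan
    pl$work_power <- p
    traj <- simulate_wbal(pl, cp, wprime)
    if (!is.na(attr(traj, "exhaustion_time"))) {
      # exhausted early: overshoot measured as remaining-depletion surplus
      return(-(plan$total_s - attr(traj, "exhaustion_time")) * (p - cp) - 1e-9)
    }
    traj$wbal_j[nrow(traj)]
  }
  lo <- cp + 1e-6
  hi <- 1e4
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (final_wbal(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
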