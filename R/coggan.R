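#' Realise a session plan as a 1-Hz power series
#'
#' Expands the plan's alternating work/rest structure into one power sample per
#' second, the input format of the Normalized Power algorithm. Sessions shorter
#' than 30 s cannot carry a single complete 30-s rolling window and are
#' rejected.
#'
#' @param plan A [session_plan()] with `work_power` set.
#' @return A tibble of class `power_series` with columns `time_s` (1, 2, ...)
#'   and `power_w`.
#' @export
#' @examples
#' build_power_series(session_plan(2, 15, 15, rest_power = 100, work_power = 400))
build_power_series <- function(plan) {
  stopifnot(inherits(plan, "session_plan"), nrow(plan) == 1)
  if (is.na(plan$work_power)) {
    abort("`plan$work_power` must be set.", class = "hiitsim_validation_error")
  }
  if (plan$total_s < 30) {
    abort("Session shorter than 30 s: too short to compute Normalized Power.",
          class = "hiitsim_series_too_short_error")
  }
  segs <- plan_segments(plan)
  samples <- rep(segs$power_w, times = segs$duration_s)
  structure(
    tibble::tibble(time_s = seq_along(samples), power_w = samples),
    class = c("power_series", class(tibble::tibble()))
  )
}

#' Normalized Power of a power series
#'
#' Implements the four-step Normalized Power algorithm: (1) average the power
#' over every 30-s rolling window, (2) raise each window mean to the fourth
#' power, (3) average those values, (4) take the fourth root. Windows are the
#' `T - 29` fully contained 30-sample windows of the 1-Hz series, stepped one
#' sample at a time; no partial or padded windows enter the mean. The fourth
#' power weights intensity spikes heavily, so NP is never below the arithmetic
#' mean, with equality exactly for a constant series.
#'
#' @param series A `power_series` tibble from [build_power_series()], or a bare
#'   numeric vector of 1-Hz power samples (W).
#' @return Normalized Power (W).
#' @export
#' @examples
#' normalized_power(rep(300, 60))           # 300
#' normalized_power(c(rep(400, 30), rep(200, 30)))
normalized_power <- function(series) {
  p <- if (is.data.frame(series)) series$power_w else as.numeric(series)
  n <- length(p)
  if (n < 30) {
    abort("Series shorter than 30 s: too short to compute Normalized Power.",
          class = "hiitsim_series_too_short_error")
  }
  if (any(p < 0)) abort("Power samples must be non-negative.",
                        class = "hiitsim_validation_error")
  cs <- c(0, cumsum(p))
  means <- (cs[31:(n + 1)] - cs[1:(n - 29)]) / 30
  mean(means^4)^0.25
}

#' Intensity Factor
#'
#' The session's Normalized Power relative to functional threshold power.
#'
#' @param pn Normalized Power (W).
#' @param ftp Functional threshold power (W), positive.
#' @return Dimensionless IF = pn / ftp.
#' @export
intensity_factor <- function(pn, ftp) {
  if (any(ftp <= 0)) abort("`ftp` must be positive.", class = "hiitsim_domain_error")
  pn / ftp
}

#' Training Stress Score
#'
#' Session training load `(pn / ftp)^2 * duration / 3600`: a one-hour effort at
#' threshold scores exactly 1. (The conventional display scaling multiplies by
#' 100; set `scale_100 = TRUE` for that. All internal logic uses the unscaled
#' form.)
#'
#' @param duration Session duration (s), positive.
#' @param pn Normalized Power (W).
#' @param ftp Functional threshold power (W), positive.
#' @param scale_100 Multiply by 100 for the conventional display scale.
#' @return Dimensionless TSS.
#' @export
#' @examples
#' tss(3600, pn = 264, ftp = 264)  # 1
tss <- function(duration, pn, ftp, scale_100 = FALSE) {
  if (any(duration <= 0)) abort("`duration` must be positive.",
                                class = "hiitsim_domain_error")
  if (any(ftp <= 0)) abort("`ftp` must be positive.", class = "hiitsim_domain_error")
  out <- (pn / ftp)^2 * duration / 3600
  if (scale_100) out * 100 else out
}

#' Maximal attainable Training Stress Score over a duration
#'
#' The TSS of a maximal effort of duration `T`, obtained by substituting the
#' athlete's best power over `T` for the Normalized Power:
#' `(pmax_T / ftp)^2 * T / 3600`. A session reaching exhaustion attains this
#' ceiling, which is what equates its NP with `pmax_T`.
#'
#' @param duration Session duration (s), positive.
#' @param pmax_t Athlete's maximal mean power over `duration` (W).
#' @param ftp Functional threshold power (W), positive.
#' @param scale_100 Multiply by 100 for the conventional display scale.
#' @return Dimensionless maximal TSS.
#' @export
tss_max <- function(duration, pmax_t, ftp, scale_100 = FALSE) {
  tss(duration, pmax_t, ftp, scale_100 = scale_100)
}

#' Coggan metrics of a session
#'
#' @param series A `power_series` or numeric 1-Hz power vector (W).
#' @param ftp Functional threshold power (W).
#' @return A one-row tibble with `duration_s`, `mean_power_w`, `pn_w`, `if_`
#'   and `tss`.
#' @export
coggan_metrics <- function(series, ftp) {
  p <- if (is.data.frame(series)) series$power_w else as.numeric(series)
  pn <- normalized_power(p)
  tibble::tibble(
    duration_s = length(p),
    mean_power_w = mean(p),
    pn_w = pn,
    if_ = intensity_factor(pn, ftp),
    tss = tss(length(p), pn, ftp)
  )
}

# Number of work samples in each fully contained 30-s window of the plan's
# 1-Hz series. NP as a function of work power P only depends on these counts:
# window mean = (k * P + (30 - k) * rest_power) / 30, so NP can be evaluated
# from the tabulated counts in O(#distinct k) instead of O(T) per solver
# iteration. Exactly equivalent to normalized_power(build_power_series(...)).
work_window_counts <- function(plan) {
  segs <- plan_segments(plan)
  ind <- rep(as.numeric(segs$is_work), times = segs$duration_s)
  n <- length(ind)
  cs <- c(0, cumsum(ind))
  counts <- cs[31:(n + 1)] - cs[1:(n - 29)]
  tab <- table(counts)
  list(k = as.numeric(names(tab)), n_k = as.numeric(tab), n_win = n - 29)
}

np_from_counts <- function(counts, work_power, rest_power) {
  wm <- (counts$k * work_power + (30 - counts$k) * rest_power) / 30
  (sum(counts$n_k * wm^4) / counts$n_win)^0.25
}

#' Work intensity whose session Normalized Power equals the duration-maximal
#' power
#'
#' Solves the constant work-interval power at which the session's Normalized
#' Power equals the athlete's maximal power over the total session duration —
#' the exhaustion condition of the Coggan-Modified model, equivalent to the
#' session TSS reaching the maximal TSS attainable over that duration. NP is
#' continuous and strictly increasing in the work power, so bisection finds
#' the unique root; the bracket is `[rest_power, 10 * pmax(work_s)]` with a
#' 200-iteration cap.
#'
#' @param plan A [session_plan()]; its `work_power` is ignored.
#' @param profile An [athlete_profile()] supplying the power-duration curve.
#' @param tol Tolerance (W) on `|NP - pmax(total_s)|` at the returned root.
#' @return The exhaustion work power P* (W).
#' @export
#' @examples
#' pr <- bundled_profiles()$time_trialist
#' plan <- session_plan(2, 15, 300, rest_power = 0.5 * pr$map)
#' solve_power_coggan(plan, pr)
solve_power_coggan <- function(plan, profile, tol = 1e-3) {
  stopifnot(inherits(plan, "session_plan"), nrow(plan) == 1,
            inherits(profile, "athlete_profile"))
  if (plan$total_s < 30) {
    abort("Session shorter than 30 s: too short to compute Normalized Power.",
          class = "hiitsim_series_too_short_error")
  }
  target <- pmax_power(profile, plan$total_s)  # errors if out of range
  counts <- work_window_counts(plan)
  np_at <- function(p) np_from_counts(counts, p, plan$rest_power)
  lo <- plan$rest_power
  if (np_at(lo) > target + tol) {
    abort("No solution: Normalized Power already exceeds the target at rest power.",
          class = "hiitsim_no_solution_error")
  }
  hi <- 10 * pmax_power(profile, plan$work_s)
  while (np_at(hi) < target) hi <- 2 * hi
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (np_at(mid) < target) lo <- mid else hi <- mid
    if ((hi - lo) < tol) break
  }
  # return the sub-target bracket edge: NP responds to a uniform work-power
  # shift by at most that shift, so |NP(lo) - target| < tol, and the solved
  # intensity never overshoots the exhaustion target (an exactly-attainable
  # target classifies as possible, not impossible-by-rounding)
  lo
}
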