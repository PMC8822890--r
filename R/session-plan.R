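#' Define a HIIT session plan
#'
#' A session is the alternating sequence work, rest, work, ..., work: `n_reps`
#' work bouts separated by `n_reps - 1` rest bouts, with no trailing rest. The
#' total duration is therefore
#' `n_reps * work_s + (n_reps - 1) * rest_s`.
#'
#' @param n_reps Number of work repetitions (>= 1).
#' @param work_s Work-interval duration (s).
#' @param rest_s Rest-interval duration (s). Ignored when `n_reps = 1`.
#' @param rest_power Power held during rest intervals (W).
#' @param work_power Power held during work intervals (W), or `NA` when it is
#'   to be solved by a model.
#' @return A one-row tibble of class `session_plan` with columns `n_reps`,
#'   `work_s`, `rest_s`, `rest_power`, `work_power`, `total_s` and
#'   `total_work_s`.
#' @export
#' @examples
#' session_plan(n_reps = 4, work_s = 60, rest_s = 120, rest_power = 150)
session_plan <- function(n_reps, work_s, rest_s, rest_power, work_power = NA_real_) {
  if (n_reps < 1 || n_reps != round(n_reps)) {
    abort("`n_reps` must be a positive integer.", class = "hiitsim_validation_error")
  }
  if (work_s <= 0 || (n_reps > 1 && rest_s <= 0)) {
    abort("Interval durations must be positive.", class = "hiitsim_validation_error")
  }
  if (rest_power < 0) {
    abort("`rest_power` must be non-negative.", class = "hiitsim_validation_error")
  }
  structure(
    tibble::tibble(
      n_reps = as.integer(n_reps),
      work_s = work_s,
      rest_s = rest_s,
      rest_power = rest_power,
      work_power = work_power,
      total_s = n_reps * work_s + (n_reps - 1) * rest_s,
      total_work_s = n_reps * work_s
    ),
    class = c("session_plan", class(tibble::tibble()))
  )
}

# Segment view of a plan: one row per constant-power segment, in order.
# Requires work_power to be set.
plan_segments <- function(plan) {
  stopifnot(nrow(plan) == 1)
  n <- plan$n_reps
  k <- 2L * n - 1L
  is_work <- rep(c(TRUE, FALSE), length.out = k)
  tibble::tibble(
    segment = seq_len(k),
    is_work = is_work,
    duration_s = ifelse(is_work, plan$work_s, plan$rest_s),
    power_w = ifelse(is_work, plan$work_power, plan$rest_power)
  )
}
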