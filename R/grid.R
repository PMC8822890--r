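#' Enumerate the HIIT session-plan grid
#'
#' Builds every combination of work-interval duration, repetition count and
#' rest-interval duration, then keeps the combinations whose total session
#' duration `n * work + (n - 1) * rest` lies inside `[min_total_s,
#' max_total_s]` (inclusive). The defaults span work and rest intervals of
#' 15 s to 5 min in 15-s increments and 2 to 20 repetitions, filtered to
#' sessions between 30 s (the shortest that supports a Normalized Power) and
#' 90 min; that filtered grid contains 6198 plans. Ordering is deterministic:
#' work, then repetitions, then rest, ascending.
#'
#' @param work_s Work-interval durations (s) to sweep.
#' @param reps Repetition counts to sweep.
#' @param rest_s Rest-interval durations (s) to sweep.
#' @param min_total_s,max_total_s Inclusive bounds on total session duration
#'   (s). Use `Inf` to disable the upper filter.
#' @return A tibble with columns `n_reps`, `work_s`, `rest_s`, `total_s` and
#'   `total_work_s`, one row per retained plan.
#' @export
#' @examples
#' nrow(generate_plans())  # 6198
generate_plans <- function(work_s = seq(15, 300, by = 15),
                           reps = 2:20,
                           rest_s = seq(15, 300, by = 15),
                           min_total_s = 30,
                           max_total_s = 5400) {
  if (length(work_s) == 0 || length(reps) == 0 || length(rest_s) == 0) {
    abort("Grid ranges must be non-empty.", class = "hiitsim_validation_error")
  }
  g <- tidyr::expand_grid(work_s = sort(work_s), n_reps = as.integer(sort(reps)),
                          rest_s = sort(rest_s))
  g <- dplyr::mutate(g,
    total_s = .data$n_reps * .data$work_s + (.data$n_reps - 1) * .data$rest_s,
    total_work_s = .data$n_reps * .data$work_s
  )
  g <- dplyr::filter(g, .data$total_s >= min_total_s, .data$total_s <= max_total_s)
  dplyr::select(g, "n_reps", "work_s", "rest_s", "total_s", "total_work_s")
}

solver_for <- function(model) {
  switch(model,
    skiba = function(plan, profile) {
      solve_power_skiba(plan, cp = profile$cp, wprime = profile$wprime)
    },
    coggan_modified = function(plan, profile) solve_power_coggan(plan, profile),
    abort(sprintf("Unknown model '%s'.", model), class = "hiitsim_validation_error")
  )
}

#' Classify one session's feasibility under a model
#'
#' Solves the exhaustion work intensity for the plan under the given model,
#' compares it with the athlete's maximal power over the work-interval
#' duration, and flags the session impossible when the solved intensity
#' strictly exceeds that bound — i.e. when reaching the model's exhaustion
#' condition would require the athlete to beat their personal best on every
#' work interval. A solved intensity exactly at the bound is possible.
#'
#' @param plan A [session_plan()] or a one-row plan tibble from
#'   [generate_plans()]; a missing `rest_power` is filled as `rest_fraction`
#'   of the profile's MAP.
#' @param profile An [athlete_profile()].
#' @param model `"skiba"` or `"coggan_modified"`.
#' @param rest_fraction Rest intensity as a fraction of MAP, used when the
#'   plan carries no `rest_power`. Default 0.5.
#' @return A one-row session-record tibble: `model`, `profile`, `n_reps`,
#'   `work_s`, `rest_s`, `rest_power_w`, `solved_power_w`, `pmax_work_w`,
#'   `ratio_pct` (solved power as a percentage of the work-duration maximum),
#'   `intensity_pct_map`, `total_s`, `total_work_s`, `impossible`,
#'   `solver_error` (a message when the solver failed, else `NA`).
#' @export
#' @examples
#' pr <- bundled_profiles()$time_trialist
#' classify_session(session_plan(2, 15, 300, rest_power = 0.5 * pr$map), pr, "skiba")
classify_session <- function(plan, profile, model = c("skiba", "coggan_modified"),
                             rest_fraction = 0.5) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "athlete_profile"), nrow(plan) == 1)
  rest_power <- if ("rest_power" %in% names(plan) && !is.na(plan$rest_power)) {
    plan$rest_power
  } else {
    rest_fraction * profile$map
  }
  pl <- session_plan(plan$n_reps, plan$work_s, plan$rest_s, rest_power)
  solve <- solver_for(model)
  solved <- NA_real_
  err <- NA_character_
  tryCatch(solved <- solve(pl, profile),
           error = function(e) err <<- conditionMessage(e))
  pmax_work <- tryCatch(pmax_power(profile, pl$work_s), error = function(e) NA_real_)
  profile_name <- profile$name
  map_w <- profile$map
  tibble::tibble(
    model = model,
    profile = profile_name,
    n_reps = pl$n_reps,
    work_s = pl$work_s,
    rest_s = pl$rest_s,
    rest_power_w = rest_power,
    solved_power_w = solved,
    pmax_work_w = pmax_work,
    ratio_pct = 100 * solved / pmax_work,
    intensity_pct_map = 100 * solved / map_w,
    total_s = pl$total_s,
    total_work_s = pl$total_work_s,
    impossible = solved > pmax_work,
    solver_error = err
  )
}

#' Run the feasibility grid for a set of profiles and models
#'
#' Solves the exhaustion work intensity for every plan under every requested
#' model and profile, and classifies each session's feasibility. The run is
#' fully deterministic. Solver failures on individual cells are recorded in
#' the `solver_error` column rather than aborting the run.
#'
#' The Skiba intensities come from the closed form and are computed
#' vectorised; the Coggan-Modified intensities are solved per plan by
#' bisection on the window-count form of Normalized Power.
#'
#' @param profiles A list of [athlete_profile()] objects (or a single one).
#' @param models Character subset of `c("skiba", "coggan_modified")`.
#' @param plans Plan grid tibble from [generate_plans()]; defaults to the full
#'   6198-plan grid.
#' @param rest_fraction Rest intensity as a fraction of each profile's MAP.
#' @return A session-record tibble, one row per (model, profile, plan), with
#'   the columns documented in [classify_session()].
#' @export
#' @examples
#' recs <- run_grid(bundled_profiles("sprinter"), models = "skiba",
#'                  plans = generate_plans(work_s = c(15, 60), rest_s = c(60, 300)))
#' dplyr::count(recs, impossible)
run_grid <- function(profiles, models = c("skiba", "coggan_modified"),
                     plans = generate_plans(), rest_fraction = 0.5) {
  if (inherits(profiles, "athlete_profile")) profiles <- list(profiles)
  models <- match.arg(models, several.ok = TRUE)
  out <- purrr::map(profiles, function(pr) {
    purrr::map(models, function(m) grid_one(plans, pr, m, rest_fraction))
  })
  dplyr::bind_rows(out)
}

grid_one <- function(plans, profile, model, rest_fraction) {
  rest_power <- rest_fraction * profile$map
  if (model == "skiba" && rest_power >= profile$cp) {
    abort("Rest power is at or above CP: the W' recovery model does not apply.",
          class = "hiitsim_model_domain_error")
  }
  if (model == "skiba") {
    lambda <- exp((rest_power - profile$cp) * plans$rest_s / profile$wprime)
    solved <- profile$cp + profile$wprime * (1 - lambda) /
      (plans$work_s * (1 - lambda^plans$n_reps))
    err <- rep(NA_character_, nrow(plans))
  } else {
    solved <- rep(NA_real_, nrow(plans))
    err <- rep(NA_character_, nrow(plans))
    for (i in seq_len(nrow(plans))) {
      pl <- session_plan(plans$n_reps[i], plans$work_s[i], plans$rest_s[i], rest_power)
      res <- tryCatch(solve_power_coggan(pl, profile),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) err[i] <- res else solved[i] <- res
    }
  }
  pmax_work <- pmax_power(profile, plans$work_s)
  profile_name <- profile$name
  map_w <- profile$map
  tibble::tibble(
    model = model,
    profile = profile_name,
    n_reps = plans$n_reps,
    work_s = plans$work_s,
    rest_s = plans$rest_s,
    rest_power_w = rest_power,
    solved_power_w = solved,
    pmax_work_w = pmax_work,
    ratio_pct = 100 * solved / pmax_work,
    intensity_pct_map = 100 * solved / map_w,
    total_s = plans$total_s,
    total_work_s = plans$total_work_s,
    impossible = solved > pmax_work,
    solver_error = err
  )
}

#' Overall percentage of impossible sessions
#'
#' @param records Session-record tibble from [run_grid()].
#' @param model,profile Optional filters; by default the percentage is
#'   computed over all supplied records.
#' @return Percentage (0-100) of records flagged impossible.
#' @export
overall_fraction <- function(records, model = NULL, profile = NULL) {
  if (!is.null(model)) records <- dplyr::filter(records, .data$model == !!model)
  if (!is.null(profile)) records <- dplyr::filter(records, .data$profile == !!profile)
  if (nrow(records) == 0) {
    abort("No records match the requested model/profile.",
          class = "hiitsim_validation_error")
  }
  100 * mean(records$impossible, na.rm = TRUE)
}

#' Impossible-session percentages within parameter subsets
#'
#' Groups the session records by one HIIT parameter and reports the impossible
#' percentage per group, per model and profile — the grouped view behind
#' feasibility-versus-parameter curves. Prescribed intensity (`%MAP`) is
#' binned into half-open intervals `[k * width, (k + 1) * width)`; the three
#' duration-type variables group on their exact grid values.
#'
#' @param records Session-record tibble from [run_grid()].
#' @param group_variable One of `"intensity_pct_map_bin"`, `"work_duration"`,
#'   `"total_work_time"`, `"rest_duration"`.
#' @param intensity_bin_width Bin width in %MAP for the intensity grouping.
#' @return A tibble of class `hiit_group_summary`: `model`, `profile`,
#'   `group_variable`, `group_value` (bin lower edge or exact seconds),
#'   `n_sessions`, `n_impossible`, `pct_impossible`.
#' @export
#' @examples
#' recs <- run_grid(bundled_profiles("sprinter"), models = "skiba")
#' summarize_sessions(recs, "work_duration")
summarize_sessions <- function(records,
                               group_variable = c("intensity_pct_map_bin",
                                                  "work_duration",
                                                  "total_work_time",
                                                  "rest_duration"),
                               intensity_bin_width = 5) {
  group_variable <- match.arg(group_variable)
  value <- switch(group_variable,
    intensity_pct_map_bin =
      floor(records$intensity_pct_map / intensity_bin_width) * intensity_bin_width,
    work_duration = records$work_s,
    total_work_time = records$total_work_s,
    rest_duration = records$rest_s
  )
  out <- records |>
    dplyr::mutate(group_value = value) |>
    dplyr::group_by(.data$model, .data$profile, .data$group_value) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      n_impossible = sum(.data$impossible, na.rm = TRUE),
      pct_impossible = 100 * .data$n_impossible / .data$n_sessions,
      .groups = "drop"
    ) |>
    dplyr::mutate(group_variable = group_variable, .before = "group_value") |>
    dplyr::arrange(.data$model, .data$profile, .data$group_value)
  structure(out, class = c("hiit_group_summary", class(out)))
}

#' Plot grouped impossible-session percentages
#'
#' @param object A `hiit_group_summary` from [summarize_sessions()].
#' @param ... Unused.
#' @return A ggplot, one panel per model, one line per profile.
#' @method autoplot hiit_group_summary
#' @export
autoplot.hiit_group_summary <- function(object, ...) {
  xlab <- switch(object$group_variable[1],
    intensity_pct_map_bin = "Prescribed intensity (%MAP, bin lower edge)",
    work_duration = "Work-interval duration (s)",
    total_work_time = "Total time at target intensity (s)",
    rest_duration = "Rest duration (s)"
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group_value,
                                       y = .data$pct_impossible,
                                       linetype = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = xlab, y = "Impossible sessions (%)") +
    ggplot2::theme_minimal()
}
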