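# Durations (s) at which profile nodes are tabulated: 1 s to 4 h.
profile_node_durations <- c(1, 15, 30, 45, 60, 120, 180, 240, 300,
                            600, 1200, 1800, 2700, 3600, 5400, 7200, 14400)

#' Generate a parametric synthetic power-duration profile
#'
#' Builds an athlete profile from three interpretable parameters so the whole
#' pipeline can be exercised on controlled inputs. Short of 5 minutes the
#' curve is hyperbolic, anchored at the maximal aerobic power:
#' `P(t) = map + wprime_syn * (1/t - 1/300)`; from 5 minutes on it declines
#' log-linearly with the endurance slope:
#' `P(t) = map * (1 + endurance_slope/100 * log10(t/300))`. The two branches
#' meet continuously at `P(300) = map`, and the curve is strictly decreasing
#' for any valid parameters. Nodes are laid down at the package's 17 standard
#' durations (1 s to 4 h); `cp` and `wprime` are then estimated from the
#' generated nodes by the 2-15-min work-duration fit ([estimate_cp_wprime()]),
#' mirroring how they would be derived from real performance data. The
#' generator is deterministic given its parameters.
#'
#' This surrogate reproduces the qualitative shape of athlete power-duration
#' curves (steep anaerobic short end, gently decaying aerobic long end); it is
#' not a physiological model.
#'
#' @param map Maximal aerobic power (W), anchored as the 5-min power.
#' @param endurance_slope Endurance, in %MAP lost per tenfold increase of
#'   duration beyond 5 min; must be negative (e.g. -10 means the 50-min power
#'   is 90% of MAP).
#' @param wprime_syn Anaerobic reserve parameter (J) shaping the sub-5-min
#'   hyperbolic branch.
#' @param body_mass Body mass (kg); metadata only.
#' @param name Profile label.
#' @return An [athlete_profile()].
#' @export
#' @examples
#' pr <- generate_profile(map = 380, endurance_slope = -9, wprime_syn = 20000)
#' pmax_power(pr, 300)  # = map
generate_profile <- function(map, endurance_slope, wprime_syn,
                             body_mass = 70, name = "synthetic") {
  if (map <= 0) abort("`map` must be positive.", class = "hiitsim_validation_error")
  if (endurance_slope >= 0) {
    abort("`endurance_slope` must be negative (%MAP per log10-decade).",
          class = "hiitsim_validation_error")
  }
  if (wprime_syn <= 0) {
    abort("`wprime_syn` must be positive.", class = "hiitsim_validation_error")
  }
  t <- profile_node_durations
  p <- ifelse(
    t < 300,
    map + wprime_syn * (1 / t - 1 / 300),
    map * (1 + endurance_slope / 100 * log10(t / 300))
  )
  if (any(p <= 0)) {
    abort("Parameters yield non-positive power at long durations; flatten the slope.",
          class = "hiitsim_validation_error")
  }
  nodes <- tibble::tibble(duration_s = t, power_w = p)
  # provisional constants so the constructor validates; replaced by the fit
  pr <- athlete_profile(name, nodes, cp = map, wprime = wprime_syn,
                        body_mass = body_mass)
  fit <- estimate_cp_wprime(pr)
  athlete_profile(name, nodes, cp = fit$cp, wprime = fit$wprime,
                  body_mass = body_mass)
}

#' Sweep endurance slope against the impossible-session fraction
#'
#' Generates one synthetic profile per endurance slope (holding `map` and
#' `wprime_syn` fixed), runs the feasibility grid for each, and tabulates the
#' percentage of impossible sessions per model. Profiles with greater
#' endurance (flatter, less negative slope) retain more power at long
#' durations, which raises both the estimated critical power and the
#' duration-maximal targets, so the impossible fraction is expected to grow as
#' the slope flattens.
#'
#' @param slopes Numeric vector (length >= 1) of endurance slopes, %MAP per
#'   log10-decade, all negative.
#' @param map,wprime_syn,body_mass Passed to [generate_profile()].
#' @param models Models to run.
#' @param plans Plan grid; defaults to the full grid. Pass a thinned
#'   [generate_plans()] for quick sweeps.
#' @param rest_fraction Rest intensity as a fraction of MAP.
#' @return A tibble with one row per (slope, model): `endurance_slope`,
#'   `model`, `n_sessions`, `n_impossible`, `pct_impossible`.
#' @export
#' @examples
#' endurance_sweep(c(-12, -8), map = 380, wprime_syn = 20000,
#'                 models = "skiba",
#'                 plans = generate_plans(work_s = seq(15, 300, 60),
#'                                        rest_s = seq(15, 300, 60)))
endurance_sweep <- function(slopes, map, wprime_syn, body_mass = 70,
                            models = c("skiba", "coggan_modified"),
                            plans = generate_plans(), rest_fraction = 0.5) {
  if (length(slopes) < 1) {
    abort("Supply at least one slope.", class = "hiitsim_validation_error")
  }
  models <- match.arg(models, several.ok = TRUE)
  purrr::map(slopes, function(sl) {
    pr <- generate_profile(map, sl, wprime_syn, body_mass = body_mass,
                           name = sprintf("slope%+g", sl))
    recs <- run_grid(pr, models = models, plans = plans,
                     rest_fraction = rest_fraction)
    recs |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(
        n_sessions = dplyr::n(),
        n_impossible = sum(.data$impossible, na.rm = TRUE),
        pct_impossible = 100 * .data$n_impossible / .data$n_sessions,
        .groups = "drop"
      ) |>
      dplyr::mutate(endurance_slope = sl, .before = 1)
  }) |>
    dplyr::bind_rows()
}
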