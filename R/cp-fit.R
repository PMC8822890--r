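#' Estimate critical power and W' by the linear work-duration fit
#'
#' Under the hyperbolic (two-parameter) critical-power model, the work an
#' athlete can produce over a maximal effort of duration t is linear in t:
#' `W(t) = W' + CP * t`. Fitting an ordinary least-squares line to work
#' (power times duration) against duration over efforts of intermediate
#' length — conventionally 2 to 15 minutes — yields CP as the slope and W' as
#' the intercept.
#'
#' @param profile An [athlete_profile()].
#' @param window Length-2 numeric, the inclusive duration window (s) whose
#'   nodes enter the fit. Default `c(120, 900)`, the conventional 2-15 min.
#' @return An object of class `cp_fit` with elements `cp` (W), `wprime` (J),
#'   `fit` (the underlying `lm`), `window` and `n_nodes`. Supports [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' fit <- estimate_cp_wprime(bundled_profiles()$time_trialist)
#' tidy(fit)
estimate_cp_wprime <- function(profile, window = c(120, 900)) {
  stopifnot(inherits(profile, "athlete_profile"), length(window) == 2)
  nodes <- dplyr::filter(
    profile$nodes,
    .data$duration_s >= window[1], .data$duration_s <= window[2]
  )
  if (nrow(nodes) < 2) {
    abort(sprintf(
      "Need at least 2 nodes in the window [%g, %g] s; found %d.",
      window[1], window[2], nrow(nodes)
    ), class = "hiitsim_insufficient_data_error")
  }
  dat <- tibble::tibble(
    duration_s = nodes$duration_s,
    work_j = nodes$power_w * nodes$duration_s
  )
  fit <- lm(work_j ~ duration_s, data = dat)
  structure(
    list(
      cp = unname(coef(fit)[["duration_s"]]),
      wprime = unname(coef(fit)[["(Intercept)"]]),
      fit = fit,
      window = window,
      n_nodes = nrow(nodes),
      profile = profile$name
    ),
    class = "cp_fit"
  )
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf(
    "<cp_fit> %s: CP = %.1f W, W' = %.2f kJ (%d nodes in [%g, %g] s)\n",
    x$profile, x$cp, x$wprime / 1000, x$n_nodes, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Tidy a critical-power fit
#'
#' @param x A `cp_fit` from [estimate_cp_wprime()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`cp`, `wprime`), its estimate,
#'   standard error and units.
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("cp", "wprime"),
    estimate = c(x$cp, x$wprime),
    std.error = c(s["duration_s", "Std. Error"], s["(Intercept)", "Std. Error"]),
    unit = c("W", "J")
  )
}

#' Glance at a critical-power fit
#'
#' @param x A `cp_fit` from [estimate_cp_wprime()].
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `n_nodes` and the fit
#'   window bounds.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n_nodes = x$n_nodes,
    window_min_s = x$window[1],
    window_max_s = x$window[2]
  )
}
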