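#' Construct an athlete power-duration profile
#'
#' An `athlete_profile` represents a cyclist's power-duration relationship as a
#' table of best mean mechanical power over a set of effort durations, together
#' with the two-parameter critical-power constants. Maximal power at durations
#' between tabulated nodes is obtained by interpolation linear in power against
#' log duration (see [pmax_power()]).
#'
#' Two summary powers are filled from the nodes: `ftp`, the functional
#' threshold power, is the best 60-minute power, and `map`, the maximal aerobic
#' power, is simplified to the best 5-minute power. Both are interpolated when
#' 3600 s / 300 s are not tabulated nodes.
#'
#' @param name Profile label.
#' @param nodes Data frame with columns `duration_s` and `power_w`: best mean
#'   power (mechanical watts) over each duration. Durations must be strictly
#'   increasing and powers strictly decreasing.
#' @param cp Critical power (W), the asymptote of the hyperbolic power-duration
#'   model: the modeled boundary between sustainable and non-sustainable
#'   intensity.
#' @param wprime Anaerobic work capacity W' (J): the finite amount of work
#'   available above `cp`.
#' @param body_mass Body mass (kg); metadata only.
#'
#' @return An object of class `athlete_profile`: a list with elements `name`,
#'   `body_mass`, `nodes` (a tibble), `cp`, `wprime`, `ftp` and `map`.
#' @seealso [load_profile()], [bundled_profiles()], [pmax_power()]
#' @export
#' @examples
#' pr <- athlete_profile(
#'   "toy",
#'   nodes = data.frame(duration_s = c(60, 300, 1200, 3600),
#'                      power_w = c(500, 380, 320, 280)),
#'   cp = 300, wprime = 20000
#' )
#' pr$map  # 5-min power
athlete_profile <- function(name, nodes, cp, wprime, body_mass = 70) {
  if (is.null(cp) || is.null(wprime) || !is.finite(cp) || !is.finite(wprime)) {
    abort("`cp` and `wprime` must both be supplied and finite.",
          class = "hiitsim_validation_error")
  }
  if (cp <= 0 || wprime <= 0) {
    abort("`cp` and `wprime` must be positive.",
          class = "hiitsim_validation_error")
  }
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("duration_s", "power_w") %in% names(nodes))) {
    abort("`nodes` needs columns `duration_s` and `power_w`.",
          class = "hiitsim_validation_error")
  }
  if (nrow(nodes) < 2) {
    abort("At least two (duration, power) nodes are required.",
          class = "hiitsim_validation_error")
  }
  d <- nodes$duration_s
  p <- nodes$power_w
  if (any(d <= 0)) {
    abort("Node durations must be positive.", class = "hiitsim_validation_error")
  }
  bad <- which(diff(d) <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Node durations must be strictly increasing; offending pair at %g s and %g s.",
      d[bad[1]], d[bad[1] + 1]
    ), class = "hiitsim_validation_error")
  }
  bad <- which(diff(p) >= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Node powers must be strictly decreasing; offending pair %g W (%g s) and %g W (%g s).",
      p[bad[1]], d[bad[1]], p[bad[1] + 1], d[bad[1] + 1]
    ), class = "hiitsim_validation_error")
  }
  out <- structure(
    list(
      name = as.character(name),
      body_mass = body_mass,
      nodes = nodes,
      cp = cp,
      wprime = wprime,
      ftp = NA_real_,
      map = NA_real_
    ),
    class = "athlete_profile"
  )
  # summary powers are NA when the node range does not cover them
  in_range <- function(s) s >= d[1] && s <= d[length(d)]
  out$ftp <- if (in_range(3600)) pmax_power(out, 3600) else NA_real_
  out$map <- if (in_range(300)) pmax_power(out, 300) else NA_real_
  out
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf(
    "<athlete_profile> %s: %d nodes over [%g, %g] s\n",
    x$name, nrow(x$nodes), min(x$nodes$duration_s), max(x$nodes$duration_s)
  ))
  cat(sprintf(
    "  CP %.0f W | W' %.1f kJ | MAP %.0f W | FTP %.0f W | mass %g kg\n",
    x$cp, x$wprime / 1000, x$map, x$ftp, x$body_mass
  ))
  invisible(x)
}

#' Maximal sustainable power over a duration
#'
#' Interpolates the profile's power-duration curve at an arbitrary duration.
#' Between nodes the curve is taken as linear in power against the logarithm of
#' duration, which keeps the interpolant strictly decreasing and reproduces the
#' tabulated node values exactly. No extrapolation is performed: a
#' power-duration curve is a fatigue model, and extending it beyond its
#' observed range is unsafe, so durations outside the tabulated span raise an
#' error.
#'
#' @param profile An [athlete_profile()].
#' @param duration Effort duration(s) in seconds, each within the tabulated
#'   node range.
#' @return Maximal mean power (W), vectorised over `duration`.
#' @export
#' @examples
#' pr <- bundled_profiles()$all_rounder
#' pmax_power(pr, c(60, 75, 300))
pmax_power <- function(profile, duration) {
  stopifnot(inherits(profile, "athlete_profile"))
  d <- profile$nodes$duration_s
  if (any(duration < d[1] | duration > d[length(d)])) {
    abort(sprintf(
      "Duration outside the tabulated range [%g, %g] s; no extrapolation.",
      d[1], d[length(d)]
    ), class = "hiitsim_range_error")
  }
  approx(log(d), profile$nodes$power_w, xout = log(duration), ties = "ordered")$y
}

#' Read an athlete profile from a YAML document
#'
#' The document schema is flat YAML: `name`, `body_mass_kg`, `cp_w`,
#' `wprime_j`, and `nodes`, a sequence of `{duration_s, power_w}` maps. Profiles
#' written by [write_profile()] (including generated synthetic profiles)
#' round-trip through this reader.
#'
#' @param path Path to a profile YAML file.
#' @return An [athlete_profile()].
#' @export
load_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  required <- c("name", "cp_w", "wprime_j", "nodes")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    abort(paste0("Profile document is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "hiitsim_validation_error")
  }
  nodes <- dplyr::bind_rows(lapply(doc$nodes, tibble::as_tibble))
  athlete_profile(
    name = doc$name,
    nodes = nodes[, c("duration_s", "power_w")],
    cp = as.numeric(doc$cp_w),
    wprime = as.numeric(doc$wprime_j),
    body_mass = if (!is.null(doc$body_mass_kg)) as.numeric(doc$body_mass_kg) else 70
  )
}

#' Write an athlete profile to a YAML document
#'
#' @param profile An [athlete_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "athlete_profile"))
  doc <- list(
    name = profile$name,
    body_mass_kg = profile$body_mass,
    cp_w = profile$cp,
    wprime_j = profile$wprime,
    nodes = purrr::pmap(profile$nodes, function(duration_s, power_w) {
      list(duration_s = duration_s, power_w = power_w)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Bundled fictitious cyclist archetypes
#'
#' Three elite-cyclist archetype profiles shipped with the package and used by
#' the packaged feasibility experiment: a Time-Trialist (high endurance, low
#' anaerobic reserve), an All-Rounder (baseline), and a Sprinter (high
#' anaerobic reserve, low endurance). Each carries 17 power-duration nodes from
#' 1 s to 4 h in mechanical watts plus its critical power and W' constants.
#'
#' @param name Optional archetype name (`"time_trialist"`, `"all_rounder"`,
#'   `"sprinter"`). Default returns all three.
#' @return A single [athlete_profile()] if `name` is given, otherwise a named
#'   list of the three.
#' @export
#' @examples
#' bundled_profiles("sprinter")
bundled_profiles <- function(name = NULL) {
  dir <- system.file("extdata", "profiles", package = "hiitsim")
  all <- c("time_trialist", "all_rounder", "sprinter")
  if (is.null(name)) {
    out <- lapply(all, function(nm) load_profile(file.path(dir, paste0(nm, ".yml"))))
    names(out) <- all
    return(out)
  }
  name <- match.arg(name, all)
  load_profile(file.path(dir, paste0(name, ".yml")))
}
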