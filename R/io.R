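session_csv_cols <- c("model", "profile", "n_reps", "work_s", "rest_s",
                      "rest_power_w", "solved_power_w", "pmax_work_w",
                      "ratio_pct", "intensity_pct_map", "total_s",
                      "total_work_s", "impossible", "solver_error")

#' Write session records to CSV
#'
#' UTF-8, header row, '.' decimal separator, fixed column order.
#'
#' @param records Session-record tibble from [run_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(records, path) {
  readr::write_csv(records[, session_csv_cols], path)
  invisible(path)
}

#' Read session records from CSV
#'
#' @param path Path to a session CSV written by [write_session_csv()].
#' @return A session-record tibble.
#' @export
read_session_csv <- function(path) {
  recs <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(setdiff(session_csv_cols, "solver_error"), names(recs))
  if (length(missing) > 0) {
    abort(paste0("Session CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hiitsim_parse_error")
  }
  recs
}

#' Run the full feasibility experiment and write its outputs
#'
#' End-to-end driver: runs the feasibility grid for the given profiles and
#' models, then writes the session-level CSV, one grouped-summary CSV per
#' grouping variable, and a YAML run manifest echoing the configuration and
#' package version.
#'
#' @param out_dir Output directory, created if needed.
#' @param profiles List of [athlete_profile()]s; defaults to the three bundled
#'   archetypes.
#' @param models Models to run.
#' @param plans Plan grid; defaults to the full 6198-plan grid.
#' @param rest_fraction Rest intensity as a fraction of MAP.
#' @param intensity_bin_width Bin width (%MAP) for the intensity summary.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the session records and the summary tibbles.
#' @export
run_experiment <- function(out_dir,
                           profiles = bundled_profiles(),
                           models = c("skiba", "coggan_modified"),
                           plans = generate_plans(),
                           rest_fraction = 0.5,
                           intensity_bin_width = 5,
                           quiet = FALSE) {
  if (inherits(profiles, "athlete_profile")) profiles <- list(profiles)
  models <- match.arg(models, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir),
          class = "hiitsim_io_error")
  }
  records <- purrr::map(profiles, function(pr) {
    purrr::map(models, function(m) {
      if (!quiet) message(sprintf("solving %s / %s ...", m, pr$name))
      grid_one(plans, pr, m, rest_fraction)
    })
  }) |> dplyr::bind_rows()
  write_session_csv(records, file.path(out_dir, "sessions.csv"))
  group_vars <- c("intensity_pct_map_bin", "work_duration",
                  "total_work_time", "rest_duration")
  summaries <- lapply(group_vars, function(gv) {
    s <- summarize_sessions(records, gv, intensity_bin_width = intensity_bin_width)
    readr::write_csv(s, file.path(out_dir, paste0("summary_", gv, ".csv")))
    s
  })
  names(summaries) <- group_vars
  manifest <- list(
    package = "hiitsim",
    version = as.character(utils::packageVersion("hiitsim")),
    profiles = vapply(profiles, function(p) p$name, character(1)),
    models = models,
    n_plans = nrow(plans),
    min_total_s = min(plans$total_s),
    max_total_s = max(plans$total_s),
    rest_fraction = rest_fraction,
    intensity_bin_width = intensity_bin_width
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(list(records = records, summaries = summaries))
}

#' Text report of impossible-session percentages
#'
#' Prints, per model, the impossible percentage for each profile and the
#' min/max across profiles.
#'
#' @param records Session-record tibble, or the path of a session CSV.
#' @return Invisibly, the per-(model, profile) percentage tibble.
#' @export
report_fractions <- function(records) {
  if (is.character(records)) records <- read_session_csv(records)
  if (nrow(records) == 0) {
    abort("No session records to report.", class = "hiitsim_parse_error")
  }
  tab <- records |>
    dplyr::group_by(.data$model, .data$profile) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      pct_impossible = 100 * mean(.data$impossible, na.rm = TRUE),
      .groups = "drop"
    )
  for (m in unique(tab$model)) {
    sub <- dplyr::filter(tab, .data$model == m)
    cat(sprintf("Model: %s\n", m))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-15s %6.2f %% impossible (n = %d)\n",
                  sub$profile[i], sub$pct_impossible[i], sub$n_sessions[i]))
    }
    cat(sprintf("  min/max across profiles: %.2f / %.2f %%\n",
                min(sub$pct_impossible), max(sub$pct_impossible)))
  }
  invisible(tab)
}

#' Export a W'-balance trajectory as CSV
#'
#' @param trajectory A `wbal_trajectory` from [simulate_wbal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(tibble::as_tibble(trajectory), path)
  invisible(path)
}
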