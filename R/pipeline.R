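#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> score -> bathing rule -> apparency ->
#' crossover screen -> randomized-trial analyses as one reproducible run.
#' When `data` is `NULL` a synthetic experiment is simulated from `params`
#' and `seed`; otherwise `data` must be a list with `beats`, `events`,
#' `groups` and `populations` (e.g. assembled from [read_beats()] and
#' [read_events()]). The same inputs and seed yield an identical bundle.
#'
#' @param data Optional pre-built dataset (skips simulation).
#' @param params Simulation parameters, used when `data` is `NULL`.
#' @param layout Experiment layout.
#' @param scenario Missingness scenario passed to [simulate_experiment()].
#' @param seed Root seed for all randomness.
#' @param k,threshold,max_span_ms OR-scoring settings, see [score_events()].
#' @param alpha Crossover screening level.
#' @param period_orientation Orientation of the period half-difference.
#' @param bathing Apply the bathing-hour replacement rule.
#' @return An object of class `apparency_run`: list with `or_table`,
#'   `apparency_by_period`, `carryover`, `period`, `screen`, `rct`,
#'   `config`, plus the input `data`.
#' @export
run_pipeline <- function(data = NULL, params = simulation_params(),
                         layout = experiment_layout(), scenario = "trial_profile",
                         seed = 1L, k = 5L, threshold = 2,
                         max_span_ms = 15000, alpha = 0.05,
                         period_orientation = "p1_minus_p2",
                         bathing = TRUE) {
  if (is.null(data)) {
    data <- simulate_experiment(params, layout, scenario = scenario,
                                seed = seed)
  }
  stopifnot(all(c("beats", "events", "groups") %in% names(data)))
  if (is.null(data$populations)) {
    data$populations <- tibble::tibble(
      participant_id = data$groups$participant_id, group = data$groups$group,
      itt = TRUE, pps = TRUE
    )
  }
  or_tbl <- score_events(data$beats, data$events, k = k,
                         threshold = threshold, max_span_ms = max_span_ms)
  or_tbl <- apply_bathing_rule(or_tbl, layout, enabled = bathing)

  app_period <- suppressMessages(compute_apparency(or_tbl, .data$period))
  # crossover uses both-period completers only
  both <- app_period |>
    dplyr::filter(!.data$undefined) |>
    dplyr::distinct(.data$participant_id, .data$period) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == 2)
  app_both <- dplyr::semi_join(app_period, both, by = "participant_id")
  co <- crossover_tests(suppressMessages(carryover_values(app_both)),
                        data$groups)
  pe <- crossover_tests(
    suppressMessages(period_values(app_both,
                                   orientation = period_orientation)),
    data$groups
  )
  screen <- screen_sounds(co, pe, alpha = alpha)
  rct <- run_rct(dplyr::filter(or_tbl, .data$period == 2),
                 screen$retained, data$populations)
  structure(list(
    or_table = or_tbl, apparency_by_period = app_period,
    carryover = co, period = pe, screen = screen, rct = rct,
    data = data,
    config = list(seed = seed, k = k, threshold = threshold,
                  max_span_ms = max_span_ms, alpha = alpha,
                  period_orientation = period_orientation, bathing = bathing,
                  n_participants = nrow(data$groups))
  ), class = "apparency_run")
}

#' @export
print.apparency_run <- function(x, ...) {
  cat("<apparency pipeline run> seed", x$config$seed, "\n")
  cat(nrow(x$or_table), "scored presentations,",
      nrow(x$data$groups), "participants\n")
  print(x$screen)
  print(x$rct)
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Emits `or_table.csv`, `apparency.csv`, `crossover_carryover.csv`,
#' `crossover_period.csv`, `diurnal.csv`, `response_ratios.csv` and a
#' `report.json` whose header echoes every threshold and seed used (full
#' provenance).
#'
#' @param run An `apparency_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(run, dir) {
  stopifnot(inherits(run, "apparency_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_or_table(run$or_table, file.path(dir, "or_table.csv"))
  write_apparency_table(run$apparency_by_period, file.path(dir, "apparency.csv"))
  readr::write_csv(run$carryover, file.path(dir, "crossover_carryover.csv"))
  readr::write_csv(run$period, file.path(dir, "crossover_period.csv"))
  readr::write_csv(run$rct$diurnal, file.path(dir, "diurnal.csv"))
  readr::write_csv(run$rct$ratios, file.path(dir, "response_ratios.csv"))
  write_report(list(
    config = run$config,
    screen = list(retained = run$screen$retained,
                  excluded = run$screen$excluded,
                  alpha = run$screen$alpha),
    itt_anova = unclass(run$rct$itt_anova),
    pps_anova = unclass(run$rct$pps_anova),
    imputation_log = run$rct$imputation_log,
    note = run$rct$note
  ), file.path(dir, "report.json"))
  invisible(dir)
}

#' Round percentages the way the printed tables do
#'
#' One decimal, half-up (so 0.05 rounds to 0.1), applied only at the
#' presentation layer; internal values stay unrounded.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
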