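#' Per-participant carryover and period statistics
#'
#' From per-period 14-hour apparency values (both periods required), the
#' carryover statistic for a participant and sound is the sum
#' `apparency(P1) + apparency(P2)` (range 0--200): a treatment-sequence
#' effect shifts this sum differently between the two randomization groups.
#' The period statistic is the half-difference
#' `(apparency(P1) - apparency(P2)) / 2`, whose group contrast exposes a
#' systematic period effect. Participants missing either period are excluded
#' with a message.
#'
#' @param apparency_by_period Apparency tibble with columns
#'   `participant_id`, `sound_code`, `period`, `apparency_pct` (e.g. from
#'   `compute_apparency(x, period)`).
#' @param orientation For the period statistic, whether the half-difference
#'   is taken as P1 - P2 (default) or P2 - P1; only the sign of group means
#'   changes, not the test.
#' @return A tibble: `participant_id`, `sound_code`, `value`.
#' @export
carryover_values <- function(apparency_by_period) {
  paired_periods(apparency_by_period) |>
    dplyr::mutate(value = .data$p1 + .data$p2) |>
    dplyr::select("participant_id", "sound_code", "value")
}

#' @rdname carryover_values
#' @export
period_values <- function(apparency_by_period,
                          orientation = c("p1_minus_p2", "p2_minus_p1")) {
  orientation <- match.arg(orientation)
  sgn <- if (orientation == "p1_minus_p2") 1 else -1
  paired_periods(apparency_by_period) |>
    dplyr::mutate(value = sgn * (.data$p1 - .data$p2) / 2) |>
    dplyr::select("participant_id", "sound_code", "value")
}

paired_periods <- function(app) {
  stopifnot(all(c("participant_id", "sound_code", "period",
                  "apparency_pct") %in% names(app)))
  wide <- app |>
    dplyr::select("participant_id", "sound_code", "period", "apparency_pct") |>
    tidyr::pivot_wider(names_from = "period", values_from = "apparency_pct",
                       names_prefix = "p")
  for (col in c("p1", "p2")) if (!col %in% names(wide)) wide[[col]] <- NA_real_
  drop <- is.na(wide$p1) | is.na(wide$p2)
  if (any(drop)) {
    message(sum(drop), " participant x sound cell(s) excluded ",
            "(apparency missing for one period)")
  }
  wide[!drop, ]
}

#' Welch's two-sample t-test (unequal variances)
#'
#' Two-tailed Welch test with Satterthwaite fractional degrees of freedom.
#' The difference in means is oriented as Group 2 minus Group 1, and the
#' confidence interval covers that difference. Degenerate inputs: zero
#' variance in both groups with equal means gives `t = 0`, `p = 1`; zero
#' variance with unequal means is flagged `degenerate` (the test statistic
#' is not defined).
#'
#' @param group1,group2 Numeric vectors, at least 2 finite values each.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `n1`, `n2`, `group1_mean`, `group2_mean`,
#'   `diff_means`, `t`, `df`, `ci_low`, `ci_high`, `p`, `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))  # t = 1.2247, df = 4, p = 0.2879
#' @export
welch_t <- function(group1, group2, conf_level = 0.95) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  base <- tibble::tibble(
    n1 = length(group1), n2 = length(group2),
    group1_mean = m1, group2_mean = m2, diff_means = m2 - m1
  )
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(dplyr::mutate(base, t = 0, df = length(group1) + length(group2) - 2,
                           ci_low = 0, ci_high = 0, p = 1, degenerate = FALSE))
    }
    return(dplyr::mutate(base, t = NA_real_, df = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(group2, group1, var.equal = FALSE,
                      conf.level = conf_level)
  dplyr::mutate(base,
    t = unname(ht$statistic), df = unname(ht$parameter),
    ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
    p = ht$p.value, degenerate = FALSE
  )
}

#' Crossover effect tables (one Welch test per sound)
#'
#' Runs [welch_t()] on a per-participant statistic (from
#' [carryover_values()] or [period_values()]) comparing the two
#' randomization groups, for every sound, producing a table shaped like the
#' published carryover/period-effect tables: group means of the
#' per-participant statistic, their Group 2 - Group 1 difference, t, the
#' fractional df, the 95% CI and the two-tailed p.
#'
#' @param values Tibble `participant_id`, `sound_code`, `value`.
#' @param groups Tibble `participant_id`, `group` (1 or 2).
#' @param conf_level Confidence level.
#' @return A tibble with one row per sound.
#' @export
crossover_tests <- function(values, groups, conf_level = 0.95) {
  v <- dplyr::inner_join(values, groups[, c("participant_id", "group")],
                         by = "participant_id")
  if (nrow(v) < nrow(values)) {
    warning(nrow(values) - nrow(v),
            " value row(s) without a group assignment dropped", call. = FALSE)
  }
  v |>
    dplyr::group_by(.data$sound_code) |>
    dplyr::group_modify(~ welch_t(.x$value[.x$group == 1],
                                  .x$value[.x$group == 2],
                                  conf_level = conf_level)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$sound_code, sound_codes()))
}

#' Screen sounds for reproducible responses
#'
#' A sound is retained when neither its carryover-effect test nor its
#' period-effect test shows a significant group difference at level `alpha`
#' (two-tailed, per-sound, no multiplicity correction — each sound is
#' screened on its own). Excluded sounds carry the failing test(s) and
#' p-value(s).
#'
#' @param carryover_stats,period_stats Tables from [crossover_tests()]; both
#'   must cover the same sound set.
#' @param alpha Screening level.
#' @return An object of class `apparency_screen`: a list with `retained`
#'   (character), `excluded` (tibble `sound_code`, `test`, `p`), the two
#'   input tables and `alpha`. `tidy()` gives the combined per-sound table.
#' @export
screen_sounds <- function(carryover_stats, period_stats, alpha = 0.05) {
  if (!setequal(carryover_stats$sound_code, period_stats$sound_code)) {
    stop("carryover and period tables cover different sound sets",
         call. = FALSE)
  }
  fails <- dplyr::bind_rows(
    dplyr::mutate(carryover_stats[, c("sound_code", "p")], test = "carryover"),
    dplyr::mutate(period_stats[, c("sound_code", "p")], test = "period")
  ) |>
    dplyr::filter(!is.na(.data$p), .data$p < alpha) |>
    dplyr::arrange(match(.data$sound_code, sound_codes())) |>
    dplyr::select("sound_code", "test", "p")
  retained <- setdiff(carryover_stats$sound_code, fails$sound_code)
  retained <- retained[order(match(retained, sound_codes()))]
  structure(list(retained = retained, excluded = fails,
                 carryover = carryover_stats, period = period_stats,
                 alpha = alpha),
            class = "apparency_screen")
}

#' @export
print.apparency_screen <- function(x, ...) {
  cat("<crossover reproducibility screen> alpha =", x$alpha, "\n")
  cat("retained (", length(x$retained), "): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    print(as.data.frame(x$excluded), row.names = FALSE)
  }
  invisible(x)
}

#' @method tidy apparency_screen
#' @export
tidy.apparency_screen <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$carryover, effect = "carryover"),
    dplyr::mutate(x$period, effect = "period")
  ) |>
    dplyr::mutate(retained = .data$sound_code %in% x$retained) |>
    dplyr::relocate("effect")
}

#' @method glance apparency_screen
#' @export
glance.apparency_screen <- function(x, ...) {
  tibble::tibble(n_sounds = length(unique(x$carryover$sound_code)),
                 n_retained = length(x$retained),
                 n_excluded = length(unique(x$excluded$sound_code)),
                 alpha = x$alpha)
}
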