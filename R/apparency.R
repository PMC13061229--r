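#' Apparency: the per-participant, per-sound salience score
#'
#' Aggregates scored presentations into apparency records at any scope.
#' Apparency is the percentage of valid presentations of a sound whose OR
#' value crossed the +/-2 threshold in either direction; presentations
#' labelled `invalid` are excluded from numerator and denominator alike.
#' Records with no valid presentations are flagged `undefined` (percentages
#' `NA`) and a count of such records is messaged so they can be tracked
#' through downstream pairwise exclusions.
#'
#' @param measurements Scored OR tibble from [score_events()].
#' @param ... Additional grouping columns (tidy-select), e.g. `period` or
#'   `daypart`, beyond the implicit `participant_id` and `sound_code`.
#'   Restrict scope by filtering `measurements` beforehand.
#' @return A tibble with one row per participant x sound (x extra groups):
#'   counts `n_total`, `n_valid`, `n_acc`, `n_dec`, `n_salient`, percentages
#'   `apparency_pct`, `acc_pct`, `dec_pct`, `unnoticed_pct`, and `undefined`.
#' @examples
#' # 14 valid presentations, 2 accelerations + 2 decelerations -> 28.571 %
#' m <- tibble::tibble(participant_id = "p01", sound_code = "M01",
#'                     label = rep(c("acceleration", "deceleration", "unnoticed"),
#'                                 c(2, 2, 10)))
#' compute_apparency(m)
#' @export
compute_apparency <- function(measurements, ...) {
  grp <- c("participant_id", "sound_code")
  out <- measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp)), ...) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_valid = sum(.data$label != "invalid"),
      n_acc = sum(.data$label == "acceleration"),
      n_dec = sum(.data$label == "deceleration"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_salient = .data$n_acc + .data$n_dec,
      undefined = .data$n_valid == 0,
      apparency_pct = ifelse(.data$undefined, NA_real_,
                             100 * .data$n_salient / .data$n_valid),
      acc_pct = ifelse(.data$undefined, NA_real_,
                       100 * .data$n_acc / .data$n_valid),
      dec_pct = ifelse(.data$undefined, NA_real_,
                       100 * .data$n_dec / .data$n_valid),
      unnoticed_pct = ifelse(.data$undefined, NA_real_,
                             100 - .data$acc_pct - .data$dec_pct)
    )
  if (any(out$undefined)) {
    message(sum(out$undefined),
            " apparency record(s) undefined (no valid presentations)")
  }
  out
}

#' Pooled acceleration/deceleration/unnoticed response ratios per sound
#'
#' Pools raw counts across participants within the scope of `measurements`:
#' each sound's acceleration (deceleration) rate is 100 x the pooled
#' acceleration (deceleration) count over the pooled valid-presentation
#' count, so the unnoticed rate completes each row to exactly 100 before
#' rounding. Pooling counts — rather than averaging per-participant
#' percentages — weights participants by their valid presentations;
#' `per_participant = TRUE` switches to the unweighted mean of
#' per-participant percentages for sensitivity analysis.
#'
#' @inheritParams compute_apparency
#' @param sounds Sound codes to report (default: all present). A requested
#'   sound absent from scope is omitted with a warning.
#' @param per_participant Average per-participant percentages instead of
#'   pooling counts.
#' @return A tibble with one row per sound: `sound_code`, `n_valid`,
#'   `acc_pct`, `dec_pct`, `unnoticed_pct`.
#' @export
response_ratios <- function(measurements, sounds = NULL,
                            per_participant = FALSE) {
  if (is.null(sounds)) sounds <- sort(unique(measurements$sound_code))
  present <- intersect(sounds, unique(measurements$sound_code))
  absent <- setdiff(sounds, present)
  if (length(absent)) {
    warning("sound(s) absent from scope, omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- dplyr::filter(measurements, .data$sound_code %in% present,
                     .data$label != "invalid")
  if (per_participant) {
    per <- compute_apparency(m)
    out <- per |>
      dplyr::group_by(.data$sound_code) |>
      dplyr::summarise(n_valid = sum(.data$n_valid),
                       acc_pct = mean(.data$acc_pct),
                       dec_pct = mean(.data$dec_pct), .groups = "drop")
  } else {
    out <- m |>
      dplyr::group_by(.data$sound_code) |>
      dplyr::summarise(
        n_valid = dplyr::n(),
        acc_pct = 100 * sum(.data$label == "acceleration") / dplyr::n(),
        dec_pct = 100 * sum(.data$label == "deceleration") / dplyr::n(),
        .groups = "drop"
      )
  }
  dplyr::mutate(out, unnoticed_pct = 100 - .data$acc_pct - .data$dec_pct)
}

#' Paired daytime vs evening apparency per participant and sound
#'
#' Splits measurements into daytime (segments A and C, 8:00--15:00) and
#' evening (segments B and D, 16:00--23:00) scopes and returns one
#' (daytime, evening) apparency pair per participant x sound. Participants
#' lacking a defined apparency on either side are excluded pairwise, with a
#' message giving the count.
#'
#' @inheritParams compute_apparency
#' @param segments Segment table mapping segment labels to dayparts.
#' @return A tibble: `participant_id`, `sound_code`, `daytime_pct`,
#'   `evening_pct`.
#' @export
diurnal_split <- function(measurements, segments = segment_table()) {
  m <- dplyr::left_join(measurements,
                        segments[, c("segment", "daypart")], by = "segment")
  if (anyNA(m$daypart)) {
    stop("measurements carry segment labels outside the segment table",
         call. = FALSE)
  }
  app <- suppressMessages(compute_apparency(m, .data$daypart))
  wide <- app |>
    dplyr::filter(!.data$undefined) |>
    dplyr::select("participant_id", "sound_code", "daypart", "apparency_pct") |>
    tidyr::pivot_wider(names_from = "daypart", values_from = "apparency_pct")
  for (col in c("daytime", "evening")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  dropped <- is.na(wide$daytime) | is.na(wide$evening)
  if (any(dropped)) {
    message(sum(dropped),
            " participant x sound pair(s) excluded (one daypart missing)")
  }
  wide |>
    dplyr::filter(!dropped) |>
    dplyr::select("participant_id", "sound_code",
                  daytime_pct = "daytime", evening_pct = "evening")
}

#' Bathing-hour exclusion and replacement
#'
#' Heart rate during the scheduled bath (21:00--22:00 in segment B) does not
#' reflect stimulus responses: measurements with onsets in that window are
#' dropped, and — to keep the per-period presentation denominator at 14 —
#' each affected participant's measurements from the following hour
#' (22:00--23:00, same segment and period) are duplicated in their place,
#' marked `interpolated = TRUE`. Participants with no segment-B exposure are
#' untouched. Set `enabled = FALSE` to analyse the raw 13-presentation
#' segment instead.
#'
#' @param measurements Scored OR tibble (or events tibble) with `onset_ms`,
#'   `segment`, `period`.
#' @param layout Experiment layout carrying the bathing window.
#' @param enabled Apply the rule?
#' @return The measurements tibble with an `interpolated` column.
#' @export
apply_bathing_rule <- function(measurements, layout = experiment_layout(),
                               enabled = TRUE) {
  if (!"interpolated" %in% names(measurements)) {
    measurements$interpolated <- FALSE
  }
  if (!enabled || nrow(measurements) == 0) return(measurements)
  hour <- (measurements$onset_ms / MS_PER_HOUR) %% 24
  in_bath <- measurements$segment == layout$bathing_segment &
    hour >= layout$bathing_start_h & hour < layout$bathing_end_h
  in_repl <- measurements$segment == layout$bathing_segment &
    hour >= layout$bathing_end_h & hour < layout$bathing_end_h + 1
  kept <- measurements[!in_bath, ]
  # every participant-period exposed in the bathing segment gets the
  # replacement hour duplicated (the bathing hour itself holds no usable data
  # whether or not presentations were logged there)
  exposed <- unique(measurements[measurements$segment == layout$bathing_segment,
                                 intersect(c("participant_id", "period"),
                                           names(measurements))])
  dup <- dplyr::semi_join(measurements[in_repl & !in_bath, ], exposed,
                          by = names(exposed))
  if (nrow(dup)) dup$interpolated <- TRUE
  dplyr::bind_rows(kept, dup)
}
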