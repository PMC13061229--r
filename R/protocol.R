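#' The 16 test sounds
#'
#' Returns the built-in table of auditory stimuli: eight "musical" sounds
#' (two piano notes) `M01`--`M08` and eight "complex" sounds (two pure tones)
#' `C09`--`C16`. Each musical sound shares its pair of frequencies with one
#' complex sound (`pair_code`); the two chord families (C + E major third and
#' C + G# augmented fifth) are each realised at four octaves, spanning
#' 130.8 Hz (C3) to 1661.4 Hz (G#6).
#'
#' @return A tibble with one row per sound and columns `code`, `timbre`
#'   (`"musical"` or `"complex"`), `freq_low_hz`, `freq_high_hz`,
#'   `pitch_names`, and `pair_code` (the code of the same-frequency sound of
#'   the other timbre).
#' @examples
#' sound_table()
#' @export
sound_table <- function() {
  base <- tibble::tribble(
    ~freq_low_hz, ~freq_high_hz, ~pitch_names,
    130.8,  164.8, "C3 + E3",
    130.8,  207.7, "C3 + G#3",
    261.6,  329.7, "C4 + E4",
    261.6,  415.4, "C4 + G#4",
    523.3,  659.3, "C5 + E5",
    523.3,  830.7, "C5 + G#5",
    1046.5, 1318.6, "C6 + E6",
    1046.5, 1661.4, "C6 + G#6"
  )
  musical <- dplyr::mutate(base,
    code = sprintf("M%02d", dplyr::row_number()),
    pair_code = sprintf("C%02d", dplyr::row_number() + 8L),
    timbre = "musical"
  )
  complex_ <- dplyr::mutate(base,
    code = sprintf("C%02d", dplyr::row_number() + 8L),
    pair_code = sprintf("M%02d", dplyr::row_number()),
    timbre = "complex"
  )
  dplyr::select(
    dplyr::bind_rows(musical, complex_),
    "code", "timbre", "freq_low_hz", "freq_high_hz", "pitch_names", "pair_code"
  )
}

#' Sound codes
#'
#' Convenience accessor for the 16 valid stimulus codes.
#' @return Character vector `M01`..`M08`, `C09`..`C16`.
#' @export
sound_codes <- function() sound_table()$code

MS_PER_HOUR <- 3.6e6

#' Stimulus segments of the three-day protocol
#'
#' The four 7-hour stimulus segments A--D. A and C are daytime windows
#' (8:00--15:00), B and D evening windows (16:00--23:00). By default A and B
#' fall on experimental Day 2 and C and D on Day 3, so the scheduled bathing
#' hour (21:00--22:00, Day 2) falls inside segment B; the mapping is
#' configurable via `day_index`.
#'
#' All on-axis times are milliseconds since 00:00 of Day 1 of the period.
#'
#' @param day_index Named integer vector mapping segment labels to the
#'   experimental day they fall on.
#' @return A tibble with columns `segment`, `daypart`, `day_index`,
#'   `clock_start_h`, `clock_end_h`, `start_ms`, `end_ms`.
#' @export
segment_table <- function(day_index = c(A = 2L, B = 2L, C = 3L, D = 3L)) {
  stopifnot(setequal(names(day_index), c("A", "B", "C", "D")))
  tb <- tibble::tibble(
    segment = c("A", "B", "C", "D"),
    daypart = c("daytime", "evening", "daytime", "evening"),
    day_index = as.integer(day_index[c("A", "B", "C", "D")]),
    clock_start_h = c(8, 16, 8, 16),
    clock_end_h = c(15, 23, 15, 23)
  )
  dplyr::mutate(tb,
    start_ms = ((day_index - 1) * 24 + clock_start_h) * MS_PER_HOUR,
    end_ms = ((day_index - 1) * 24 + clock_end_h) * MS_PER_HOUR
  )
}

#' Experiment layout
#'
#' Bundles the structural constants of the stimulus protocol: 16 sounds, each
#' presented once per stimulus hour, in two 7-hour segments per period per
#' group; inter-onset gaps of 225 +/- 30 s; a bathing hour (21:00--22:00 in
#' segment B) with no presentations; and the crossover mapping of
#' randomization groups to segment pairs (Group 1: A and D in period 1,
#' B and C in period 2; Group 2 the converse, unless overridden).
#'
#' @param segments Segment table, see [segment_table()].
#' @param group1_period1 Segment pair received by Group 1 in Period 1; Group 2
#'   receives the complementary pair, and the pairs swap in Period 2.
#' @param inter_onset_mean_s,inter_onset_halfwidth_s Uniform inter-onset gap
#'   distribution, in seconds: gaps are drawn from
#'   `[mean - halfwidth, mean + halfwidth]`.
#' @param bathing_segment,bathing_start_h,bathing_end_h The excluded bathing
#'   hour (clock hours).
#' @return A list of class `apparency_layout`.
#' @export
experiment_layout <- function(segments = segment_table(),
                              group1_period1 = c("A", "D"),
                              inter_onset_mean_s = 225,
                              inter_onset_halfwidth_s = 30,
                              bathing_segment = "B",
                              bathing_start_h = 21,
                              bathing_end_h = 22) {
  stopifnot(
    all(group1_period1 %in% segments$segment),
    length(group1_period1) == 2,
    inter_onset_halfwidth_s >= 0,
    inter_onset_halfwidth_s < inter_onset_mean_s
  )
  other <- setdiff(segments$segment, group1_period1)
  structure(list(
    segments = segments,
    presentations_per_hour = 16L,
    hours_per_segment = 7L,
    inter_onset_mean_s = inter_onset_mean_s,
    inter_onset_halfwidth_s = inter_onset_halfwidth_s,
    bathing_segment = bathing_segment,
    bathing_start_h = bathing_start_h,
    bathing_end_h = bathing_end_h,
    # group -> period -> segment pair
    group_segments = list(
      `1` = list(`1` = group1_period1, `2` = other),
      `2` = list(`1` = other, `2` = group1_period1)
    ),
    # waking windows (ms on the period axis) used by the RRI simulator;
    # sleep is 23:30--7:30 and stimuli occur on Days 2-3 only, so Day 1 is
    # not simulated
    waking_windows = tibble::tibble(
      day = c(2L, 3L),
      start_ms = (c(1, 2) * 24 + 7.5) * MS_PER_HOUR,
      end_ms = (c(1, 2) * 24 + 23.5) * MS_PER_HOUR
    )
  ), class = "apparency_layout")
}

#' Stimulus hours of a segment
#'
#' Clock-hour start times (on the period axis, ms) of the stimulus hours of
#' one segment, omitting the bathing hour where applicable.
#'
#' @param layout An [experiment_layout()].
#' @param segment Segment label.
#' @return Numeric vector of hour-start times in ms.
#' @export
stimulus_hours <- function(layout, segment) {
  seg <- layout$segments[layout$segments$segment == segment, ]
  if (nrow(seg) != 1) stop("unknown segment: ", segment, call. = FALSE)
  hours <- seq(seg$clock_start_h, seg$clock_end_h - 1)
  if (identical(segment, layout$bathing_segment)) {
    hours <- hours[!(hours >= layout$bathing_start_h & hours < layout$bathing_end_h)]
  }
  ((seg$day_index - 1) * 24 + hours) * MS_PER_HOUR
}

#' @export
print.apparency_layout <- function(x, ...) {
  cat("<apparency experiment layout>\n")
  cat("  16 sounds x", x$hours_per_segment, "hours per segment, 2 segments per group per period\n")
  cat("  inter-onset gap:", x$inter_onset_mean_s, "+/-", x$inter_onset_halfwidth_s, "s\n")
  cat("  bathing hour:", x$bathing_segment,
      sprintf("%02d:00-%02d:00\n", x$bathing_start_h, x$bathing_end_h))
  invisible(x)
}
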