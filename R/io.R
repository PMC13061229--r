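#' Read beat-time series
#'
#' Reads per-participant heartbeat timestamps from a CSV file with header
#' columns `participant_id` and `t_ms` (and optionally `period`), derives RR
#' intervals as successive differences, and flags each interval for
#' physiological plausibility. Beat files carry beat times only; intervals are
#' always derived, never stored.
#'
#' @param path Path to a CSV file.
#' @param rri_min_ms,rri_max_ms Plausibility bounds: intervals outside
#'   `[rri_min_ms, rri_max_ms]` are flagged invalid.
#' @return A tibble with one row per beat: `participant_id`, (`period`,)
#'   `t_ms`, `rri_ms` (the interval starting at this beat; `NA` for the last
#'   beat of a participant) and `beat_valid`.
#' @export
read_beats <- function(path, rri_min_ms = 300, rri_max_ms = 2000) {
  df <- read_table_file(path, required = c("participant_id", "t_ms"),
                        optional = "period")
  if (nrow(df) == 0) stop("empty beats file: ", path, call. = FALSE)
  df$participant_id <- as.character(df$participant_id)
  df$t_ms <- as.numeric(df$t_ms)
  keys <- beat_keys(df)
  # check monotonicity in file order, per participant
  for (k in unique(keys)) {
    t <- df$t_ms[keys == k]
    rows <- which(keys == k)
    nonmono <- which(diff(t) <= 0)
    if (length(nonmono)) {
      stop(sprintf(
        "non-monotone beat times for participant '%s' at file row %d",
        df$participant_id[rows[1]], rows[nonmono[1] + 1]), call. = FALSE)
    }
  }
  derive_rri(tibble::as_tibble(df), rri_min_ms, rri_max_ms)
}

beat_keys <- function(df) {
  if ("period" %in% names(df)) paste(df$participant_id, df$period, sep = "\r")
  else df$participant_id
}

#' Derive RR intervals and validity flags on a beats table
#'
#' @param beats Tibble with `participant_id`, `t_ms` and optionally `period`.
#' @inheritParams read_beats
#' @return The input with `rri_ms` and `beat_valid` columns (re)computed.
#' @export
derive_rri <- function(beats, rri_min_ms = 300, rri_max_ms = 2000) {
  grp <- intersect(c("participant_id", "period"), names(beats))
  beats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$t_ms, .by_group = TRUE) |>
    dplyr::mutate(
      rri_ms = dplyr::lead(.data$t_ms) - .data$t_ms,
      beat_valid = .data$rri_ms >= rri_min_ms & .data$rri_ms <= rri_max_ms
    ) |>
    dplyr::ungroup()
}

#' @rdname read_beats
#' @param beats A beats tibble.
#' @export
write_beats <- function(beats, path) {
  cols <- intersect(c("participant_id", "period", "t_ms"), names(beats))
  readr::write_csv(beats[cols], path)
  invisible(path)
}

#' Read a stimulus event log
#'
#' Reads stimulus presentations from a CSV with columns `participant_id`,
#' `sound_code`, `onset_ms`, `segment`, `period` (plus any of
#' `presentation_index`, `interpolated`). Sound codes outside the 16-sound
#' table are an error; onsets outside their segment's clock window are a
#' warning (or an error with `strict = TRUE`); duplicate
#' participant/period/sound/segment-hour combinations are reported.
#'
#' @param path Path to a CSV file.
#' @param segments Segment table used for the window check.
#' @param strict Escalate out-of-window onsets to an error.
#' @return A tibble of validated events.
#' @export
read_events <- function(path, segments = segment_table(), strict = FALSE) {
  df <- read_table_file(
    path,
    required = c("participant_id", "sound_code", "onset_ms", "segment", "period"),
    optional = c("presentation_index", "interpolated", "group", "injected")
  )
  df$participant_id <- as.character(df$participant_id)
  df$onset_ms <- as.numeric(df$onset_ms)
  df$period <- as.integer(df$period)
  validate_events(tibble::as_tibble(df), segments, strict)
}

validate_events <- function(events, segments = segment_table(), strict = FALSE) {
  bad_code <- setdiff(unique(events$sound_code), sound_codes())
  if (length(bad_code)) {
    stop("unknown sound code(s): ", paste(bad_code, collapse = ", "),
         call. = FALSE)
  }
  ev <- dplyr::left_join(events, segments, by = "segment")
  if (anyNA(ev$start_ms)) {
    stop("unknown segment label(s): ",
         paste(unique(events$segment[is.na(ev$start_ms)]), collapse = ", "),
         call. = FALSE)
  }
  outside <- ev$onset_ms < ev$start_ms | ev$onset_ms >= ev$end_ms
  if (any(outside)) {
    msg <- sprintf("%d event onset(s) fall outside their segment window",
                   sum(outside))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  hour <- floor(events$onset_ms / MS_PER_HOUR)
  key <- paste(events$participant_id, events$period, events$sound_code, hour)
  dup <- duplicated(key)
  if (any(dup)) {
    warning("duplicate presentation rows: ",
            paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  }
  events
}

#' @rdname read_events
#' @param events An events tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Write / read a scored OR table
#'
#' The on-disk OR table has deterministic column order: `participant_id`,
#' `sound_code`, `period`, `segment`, `onset_ms`, `m1_ms`, `m2_ms`, `sd_ms`,
#' `or_value`, `label`; extra columns (e.g. `interpolated`) follow. Labels are
#' spelled `acceleration`, `deceleration`, `unnoticed`, `invalid`. An empty
#' measurement set yields a header-only file. Values round-trip to full
#' double precision.
#'
#' @param measurements A scored OR tibble, see [score_events()].
#' @param path File path.
#' @export
write_or_table <- function(measurements, path) {
  lead <- c("participant_id", "sound_code", "period", "segment", "onset_ms",
            "m1_ms", "m2_ms", "sd_ms", "or_value", "label")
  lead <- intersect(lead, names(measurements))
  out <- measurements[c(lead, setdiff(names(measurements), lead))]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_or_table
#' @export
read_or_table <- function(path) {
  df <- read_table_file(path, required = c("participant_id", "sound_code",
                                           "m1_ms", "m2_ms", "sd_ms",
                                           "or_value", "label"),
                        optional = c("period", "segment", "onset_ms",
                                     "presentation_index", "interpolated",
                                     "group", "injected"))
  df$participant_id <- as.character(df$participant_id)
  ok <- df$label %in% c("acceleration", "deceleration", "unnoticed", "invalid")
  if (!all(ok)) stop("unknown OR label(s): ",
                     paste(unique(df$label[!ok]), collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}

#' Write / read an apparency table
#' @param records An apparency tibble, see [compute_apparency()].
#' @param path File path.
#' @export
write_apparency_table <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_apparency_table
#' @export
read_apparency_table <- function(path) {
  df <- read_table_file(path, required = c("participant_id", "sound_code",
                                           "n_valid", "apparency_pct"),
                        optional = c("period", "segment", "n_total",
                                     "n_salient", "n_acc", "n_dec", "acc_pct",
                                     "dec_pct", "unnoticed_pct", "undefined"))
  df$participant_id <- as.character(df$participant_id)
  tibble::as_tibble(df)
}

#' Write a statistics report
#'
#' Serialises a (possibly nested) list of statistics — each leaf a number,
#' string, or small vector — as structured JSON text, preserving full double
#' precision.
#'
#' @param stats A named list.
#' @param path File path.
#' @export
write_report <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a supplementary replication table
#'
#' Thin adapter for externally supplied per-observation or apparency tables
#' (e.g. trial appendix spreadsheets): reads an `.xlsx` sheet (via readxl,
#' when installed) or a CSV, then renames columns to the package's internal
#' names through an explicit mapping, because external sheet schemas vary.
#'
#' @param path Path to an `.xlsx` or delimited text file.
#' @param mapping Named character vector, `internal_name = "source column"`.
#' @param sheet Sheet name or index, for xlsx input.
#' @return A tibble with the mapped (and any unmapped) columns.
#' @export
read_supplementary_table <- function(path, mapping = NULL, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    }
    df <- readxl::read_excel(path, sheet = sheet)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(df))
    if (length(missing_src)) {
      stop("mapped source column(s) absent: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    idx <- match(unname(mapping), names(df))
    names(df)[idx] <- names(mapping)
  }
  tibble::as_tibble(df)
}

# shared CSV reader with strict column policy: required columns must exist,
# unknown columns draw a warning, malformed rows are an error (readr problems)
read_table_file <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed rows in ", path, " (first at row ", probs$row[1], ")",
         call. = FALSE)
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df
}
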