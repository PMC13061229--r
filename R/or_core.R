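#' Extract the pre/post RR-interval windows around one stimulus onset
#'
#' The pre window holds the last `k` RR intervals that end at or before the
#' onset; the post window holds the first `k` intervals that begin at or
#' after it. An interval straddling the onset mixes pre- and post-stimulus
#' physiology and belongs to neither window; an interval ending exactly at
#' the onset is pre, one beginning exactly at the onset is post. The pair is
#' incomplete when either side has fewer than `k` intervals within
#' `max_span_ms` of the onset (which also guards against windows bridging
#' recording gaps such as sleep), and marks itself invalid when any member
#' interval carries an implausibility flag.
#'
#' @param beats Beats tibble for a single participant (and period), with
#'   `t_ms` and optionally `beat_valid` (see [derive_rri()]).
#' @param onset_ms Stimulus onset, ms.
#' @param k Window length in intervals; the method uses 5.
#' @param max_span_ms Maximum allowed time from onset to the far end of each
#'   window.
#' @return A list of class `window_pair`: `pre_rri_ms`, `post_rri_ms`,
#'   `onset_ms`, `complete`, `valid`.
#' @export
extract_window_pair <- function(beats, onset_ms, k = 5L, max_span_ms = 15000) {
  stopifnot(length(onset_ms) == 1, nrow(beats) >= 1)
  if (length(unique(beats$participant_id)) > 1) {
    stop("beats must belong to a single participant", call. = FALSE)
  }
  t <- sort(beats$t_ms)
  r <- diff(t)
  valid <- if ("beat_valid" %in% names(beats)) {
    beats$beat_valid[order(beats$t_ms)][seq_along(r)]
  } else rep(TRUE, length(r))
  w <- locate_windows(t, onset_ms, k, max_span_ms)
  pre <- if (w$complete) r[w$pre_idx[1, ]] else numeric(0)
  post <- if (w$complete) r[w$post_idx[1, ]] else numeric(0)
  ok <- w$complete && all(valid[c(w$pre_idx[1, ], w$post_idx[1, ])], na.rm = FALSE)
  structure(list(
    pre_rri_ms = pre, post_rri_ms = post, onset_ms = onset_ms,
    complete = w$complete, valid = isTRUE(ok)
  ), class = "window_pair")
}

# vectorised window location over many onsets on one sorted beat-time vector.
# Returns completeness and k-column index matrices into the interval vector.
locate_windows <- function(t, onsets, k, max_span_ms) {
  n_int <- length(t) - 1L
  idx <- findInterval(onsets, t)            # t[idx] <= onset < t[idx+1]
  at_beat <- idx >= 1L & idx <= length(t) & t[pmax(idx, 1L)] == onsets
  post_start <- ifelse(at_beat, idx, idx + 1L)   # straddling interval skipped
  pre_start <- idx - k                            # intervals pre_start..idx-1
  in_range <- pre_start >= 1L & (post_start + k - 1L) <= n_int & idx >= 1L
  complete <- in_range
  if (any(in_range)) {
    # span guard: earliest pre beat and latest post beat near enough to onset
    ps <- pre_start[in_range]
    qs <- post_start[in_range]
    span_ok <- (onsets[in_range] - t[ps]) <= max_span_ms &
      (t[qs + k] - onsets[in_range]) <= max_span_ms
    complete[in_range] <- span_ok
  }
  offs <- seq_len(k) - 1L
  pre_idx <- outer(ifelse(complete, pre_start, NA_integer_), offs, `+`)
  post_idx <- outer(ifelse(complete, post_start, NA_integer_), offs, `+`)
  list(complete = complete, pre_idx = pre_idx, post_idx = post_idx)
}

#' Compute the orienting-response statistic for one window pair
#'
#' The OR value is `(M1 - M2) / SD`, where `M1` and `SD` are the mean and
#' sample standard deviation (divisor `k - 1`) of the pre-stimulus RR
#' intervals and `M2` the mean of the post-stimulus intervals. Shortened
#' post-stimulus intervals (heart-rate acceleration) give a positive OR.
#' Classification uses strict inequalities: `acceleration` when
#' `OR > threshold`, `deceleration` when `OR < -threshold`, otherwise
#' `unnoticed`; an incomplete or artifact-contaminated pair, or a
#' zero-variance pre window, is `invalid` with undefined OR.
#'
#' @param pair A `window_pair` from [extract_window_pair()].
#' @param threshold Classification threshold on `|OR|`; the method uses 2.
#' @return A one-row tibble: `m1_ms`, `m2_ms`, `sd_ms`, `or_value`, `label`.
#' @examples
#' p <- structure(list(pre_rri_ms = c(800, 810, 790, 805, 795),
#'                     post_rri_ms = c(760, 765, 770, 755, 750),
#'                     onset_ms = 0, complete = TRUE, valid = TRUE),
#'                class = "window_pair")
#' compute_or(p)
#' @export
compute_or <- function(pair, threshold = 2) {
  if (!isTRUE(pair$complete) || !isTRUE(pair$valid)) {
    return(tibble::tibble(m1_ms = NA_real_, m2_ms = NA_real_, sd_ms = NA_real_,
                          or_value = NA_real_, label = "invalid"))
  }
  m1 <- mean(pair$pre_rri_ms)
  m2 <- mean(pair$post_rri_ms)
  sd1 <- stats::sd(pair$pre_rri_ms)
  if (sd1 == 0) {
    return(tibble::tibble(m1_ms = m1, m2_ms = m2, sd_ms = 0,
                          or_value = NA_real_, label = "invalid"))
  }
  or <- (m1 - m2) / sd1
  tibble::tibble(m1_ms = m1, m2_ms = m2, sd_ms = sd1, or_value = or,
                 label = classify_or(or, threshold))
}

classify_or <- function(or, threshold = 2) {
  dplyr::case_when(
    is.na(or) ~ "invalid",
    or > threshold ~ "acceleration",
    or < -threshold ~ "deceleration",
    TRUE ~ "unnoticed"
  )
}

#' Score all stimulus presentations against a beat record
#'
#' Applies [extract_window_pair()] and [compute_or()] to every event,
#' matching events to beats by participant (and period, when present).
#' Events whose windows are incomplete, bridge a gap, or contain an
#' implausible interval are labelled `invalid` rather than dropped, so the
#' output has exactly one row per event, in event order.
#'
#' @param beats Beats tibble (any number of participants), see
#'   [read_beats()]/[derive_rri()].
#' @param events Events tibble, see [read_events()].
#' @param k Intervals per window.
#' @param threshold Classification threshold on `|OR|`.
#' @param max_span_ms Per-side window span guard, ms.
#' @return The events tibble augmented with `m1_ms`, `m2_ms`, `sd_ms`,
#'   `or_value`, `label`.
#' @export
score_events <- function(beats, events, k = 5L, threshold = 2,
                         max_span_ms = 15000) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  if (!"beat_valid" %in% names(beats)) beats <- derive_rri(beats)
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, m1_ms = numeric(0), m2_ms = numeric(0),
                         sd_ms = numeric(0), or_value = numeric(0),
                         label = character(0)))
  }
  grp <- intersect(c("participant_id", "period"), names(events))
  grp <- intersect(grp, names(beats))
  events$.row <- seq_len(nrow(events))
  ev_split <- split(events, events[grp], drop = TRUE)
  bt_split <- split(beats, beats[grp], drop = TRUE)
  res <- purrr::map(ev_split, function(ev) {
    key <- paste(unlist(ev[1, grp]), collapse = ".")
    bt <- bt_split[[key]]
    if (is.null(bt) || nrow(bt) < 2) {
      return(dplyr::mutate(ev, m1_ms = NA_real_, m2_ms = NA_real_,
                           sd_ms = NA_real_, or_value = NA_real_,
                           label = "invalid"))
    }
    ord <- order(bt$t_ms)
    t <- bt$t_ms[ord]
    r <- diff(t)
    valid <- bt$beat_valid[ord][seq_along(r)]
    w <- locate_windows(t, ev$onset_ms, k, max_span_ms)
    pre <- matrix(r[w$pre_idx], nrow = nrow(ev))
    post <- matrix(r[w$post_idx], nrow = nrow(ev))
    vl <- matrix(valid[w$pre_idx], nrow = nrow(ev)) &
      matrix(valid[w$post_idx], nrow = nrow(ev))
    usable <- w$complete & rowSums(!vl) == 0 & !is.na(rowSums(vl))
    m1 <- rowMeans(pre)
    m2 <- rowMeans(post)
    sd1 <- sqrt(rowSums((pre - m1)^2) / (k - 1))
    or <- ifelse(usable & sd1 > 0, (m1 - m2) / sd1, NA_real_)
    dplyr::mutate(ev,
      m1_ms = ifelse(usable, m1, NA_real_),
      m2_ms = ifelse(usable, m2, NA_real_),
      sd_ms = ifelse(usable, sd1, NA_real_),
      or_value = or,
      label = classify_or(or, threshold)
    )
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(out$.row), ]
  out$.row <- NULL
  out
}

#' @export
print.window_pair <- function(x, ...) {
  cat("<window pair> onset", x$onset_ms, "ms;",
      if (x$complete) "complete" else "incomplete",
      if (!x$valid) "(invalid)" else "", "\n")
  if (x$complete) {
    cat("  pre :", paste(signif(x$pre_rri_ms, 6), collapse = " "), "\n")
    cat("  post:", paste(signif(x$post_rri_ms, 6), collapse = " "), "\n")
  }
  invisible(x)
}
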