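#' Simulation parameters
#'
#' Study-condition defaults for the synthetic three-day, two-period
#' protocol: 22 participants randomized 1:1 in permuted blocks of 4 and 6;
#' RR intervals around an 850 ms baseline with 25 ms Gaussian noise
#' (i.i.d. by default — `ar1_coeff = 0` and `diurnal_drift_ms = 0` — so the
#' closed-form null distribution of the OR statistic holds exactly); each
#' presentation independently elicits an acceleration with probability
#' `p_acc` or a deceleration with probability `p_dec`, implemented as a
#' rectangular -/+ `response_delta_ms` shift over exactly
#' `response_len_beats` post-onset intervals (so the injected effect maps
#' analytically to an expected OR of about `response_delta_ms /
#' rri_noise_sd_ms`). The default delta of 250 ms (10 noise SDs) makes
#' injected responses essentially always cross the +/-2 threshold.
#'
#' @param n_participants Number randomized.
#' @param block_sizes Permuted-block sizes for 1:1 allocation.
#' @param baseline_rri_ms Mean RR interval.
#' @param rri_noise_sd_ms Marginal SD of the RRI noise.
#' @param ar1_coeff Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param diurnal_drift_ms Amplitude of a 24-h sinusoidal drift of the
#'   baseline (peak near 04:00, when the heart is slowest); 0 disables it.
#' @param p_acc,p_dec Per-presentation probabilities of an injected
#'   acceleration / deceleration response (`p_acc + p_dec <= 1`).
#' @param response_delta_ms Magnitude of the rectangular RRI shift.
#' @param response_len_beats Number of shifted post-onset intervals.
#' @param rri_min_ms,rri_max_ms Plausibility bounds used when flagging.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_participants = 22L,
                              block_sizes = c(4L, 6L),
                              baseline_rri_ms = 850,
                              rri_noise_sd_ms = 25,
                              ar1_coeff = 0,
                              diurnal_drift_ms = 0,
                              p_acc = 0.15,
                              p_dec = 0.15,
                              response_delta_ms = 250,
                              response_len_beats = 5L,
                              rri_min_ms = 300,
                              rri_max_ms = 2000) {
  stopifnot(
    n_participants >= 2,
    p_acc >= 0, p_dec >= 0, p_acc + p_dec <= 1,
    rri_noise_sd_ms >= 0, diurnal_drift_ms >= 0,
    ar1_coeff >= 0, ar1_coeff < 1,
    baseline_rri_ms > 0, response_len_beats >= 1
  )
  structure(as.list(environment()), class = "simulation_params")
}

#' Block randomization to two groups
#'
#' 1:1 allocation in permuted blocks whose sizes are drawn from
#' `block_sizes` in random order; the final block is truncated at
#' `n`, so the realised split can be mildly unbalanced (as happens in real
#' trials that stop recruitment mid-block).
#'
#' @param n Number of participants (ids `p01`, `p02`, ...).
#' @param block_sizes Allowed block sizes (must be even).
#' @return Tibble `participant_id`, `group` (integer 1/2).
#' @export
randomize_groups <- function(n, block_sizes = c(4L, 6L)) {
  stopifnot(all(block_sizes %% 2 == 0))
  assign <- integer(0)
  while (length(assign) < n) {
    b <- if (length(block_sizes) == 1) block_sizes else sample(block_sizes, 1)
    assign <- c(assign, sample(rep(1:2, b / 2)))
  }
  tibble::tibble(participant_id = sprintf("p%02d", seq_len(n)),
                 group = assign[seq_len(n)])
}

# onsets (s from hour start) for one stimulus hour: lead-in + 15 gaps drawn
# uniformly and kept within their stated bounds by conditioning the gap sum
# on fitting the hour (rejection), rather than rescaling individual gaps
sample_hour_onsets <- function(n_sounds, gap_lo_s, gap_hi_s, hour_s = 3600) {
  if ((n_sounds - 1) * gap_lo_s >= hour_s) {
    stop("infeasible layout: hour too short for ", n_sounds,
         " presentations at a minimum gap of ", gap_lo_s, " s", call. = FALSE)
  }
  for (try in 1:1000) {
    g <- stats::runif(n_sounds - 1, gap_lo_s, gap_hi_s)
    slack <- hour_s - sum(g)
    if (slack > 1) {
      lead <- stats::runif(1, 0, slack)
      return(lead + c(0, cumsum(g)))
    }
  }
  stop("could not fit ", n_sounds, " presentations into one hour", call. = FALSE)
}

#' Build a stimulus schedule
#'
#' For every participant, period, assigned segment and stimulus hour, the 16
#' sounds are presented once each in a fresh uniform random order, with
#' inter-onset gaps drawn uniformly from
#' `[mean - halfwidth, mean + halfwidth]` seconds (225 +/- 30 by default).
#' The bathing hour of segment B contains no presentations. Deterministic
#' given the RNG state (use `set.seed()` or [simulate_experiment()]).
#'
#' @param groups Group-assignment tibble from [randomize_groups()].
#' @param layout An [experiment_layout()].
#' @param periods Periods to schedule.
#' @return Events tibble: `participant_id`, `group`, `period`, `segment`,
#'   `sound_code`, `onset_ms`, `presentation_index` (per participant x
#'   period x sound, in onset order).
#' @export
build_schedule <- function(groups, layout = experiment_layout(),
                           periods = 1:2) {
  codes <- sound_codes()
  gap_lo <- layout$inter_onset_mean_s - layout$inter_onset_halfwidth_s
  gap_hi <- layout$inter_onset_mean_s + layout$inter_onset_halfwidth_s
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    pid <- groups$participant_id[i]
    grp <- as.character(groups$group[i])
    for (per in periods) {
      for (seg in layout$group_segments[[grp]][[as.character(per)]]) {
        for (h0 in stimulus_hours(layout, seg)) {
          onsets <- sample_hour_onsets(layout$presentations_per_hour,
                                       gap_lo, gap_hi)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant_id = pid, group = groups$group[i], period = per,
            segment = seg, sound_code = sample(codes),
            onset_ms = h0 + onsets * 1000
          )
        }
      }
    }
  }
  ev <- dplyr::bind_rows(rows)
  ev |>
    dplyr::group_by(.data$participant_id, .data$period, .data$sound_code) |>
    dplyr::arrange(.data$onset_ms, .by_group = TRUE) |>
    dplyr::mutate(presentation_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$period, .data$onset_ms)
}

#' Simulate RR-interval beat streams with injectable orienting responses
#'
#' Generates beat times for each participant and period over the waking
#' windows of the two stimulus days (sleep, 23:30--7:30, holds no beats:
#' recording is excluded there). RR intervals are
#' `baseline + drift + AR(1) Gaussian noise`; for every scheduled event an
#' outcome is drawn from (acceleration, deceleration, none) with
#' probabilities `(p_acc, p_dec, 1 - p_acc - p_dec)`; an acceleration
#' subtracts `response_delta_ms` from the `response_len_beats` intervals
#' beginning at or after the onset, a deceleration adds it. Events are
#' processed in onset order so each injection lands on the beats as already
#' shifted by earlier responses.
#'
#' @param events Schedule from [build_schedule()].
#' @param params A [simulation_params()] object.
#' @param layout Layout supplying the waking windows.
#' @return A beats tibble (`participant_id`, `period`, `t_ms`, `rri_ms`,
#'   `beat_valid`) with attribute `"outcomes"`: a tibble of the per-event
#'   injected outcome (`"acc"`, `"dec"`, `"none"`), row-aligned with
#'   `events`.
#' @export
simulate_beats <- function(events, params = simulation_params(),
                           layout = experiment_layout()) {
  stopifnot(inherits(params, "simulation_params"))
  probs <- c(acc = params$p_acc, dec = params$p_dec,
             none = 1 - params$p_acc - params$p_dec)
  events$.row <- seq_len(nrow(events))
  # outcomes drawn in event-table order for reproducibility
  outcome <- sample(names(probs), nrow(events), replace = TRUE, prob = probs)
  min_rri <- params$baseline_rri_ms - params$diurnal_drift_ms -
    params$response_delta_ms * (params$p_acc > 0) - 6 * params$rri_noise_sd_ms
  if (min_rri <= 0) {
    stop("parameters can produce non-positive RR intervals", call. = FALSE)
  }
  keys <- unique(events[, c("participant_id", "period")])
  beats <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- events$participant_id == keys$participant_id[i] &
      events$period == keys$period[i]
    ev <- events[sel, ]
    ev_out <- outcome[sel]
    blocks <- purrr::pmap(layout$waking_windows, function(day, start_ms, end_ms) {
      simulate_block(start_ms, end_ms,
                     ev$onset_ms[ev$onset_ms >= start_ms & ev$onset_ms < end_ms],
                     ev_out[ev$onset_ms >= start_ms & ev$onset_ms < end_ms],
                     params)
    })
    beats[[i]] <- tibble::tibble(
      participant_id = keys$participant_id[i],
      period = keys$period[i],
      t_ms = unlist(blocks)
    )
  }
  out <- derive_rri(dplyr::bind_rows(beats), params$rri_min_ms,
                    params$rri_max_ms)
  attr(out, "outcomes") <- tibble::tibble(.row = events$.row,
                                          injected = outcome) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select("injected")
  out
}

# one contiguous waking block: baseline + drift + AR(1) noise, then
# sequential response injection (earlier injections shift later beats, so
# each event's landing interval is located under the accumulated shift)
simulate_block <- function(start_ms, end_ms, onsets, outcomes, params) {
  span <- end_ms - start_ms
  n_int <- ceiling(span / (params$baseline_rri_ms -
                             params$diurnal_drift_ms)) + 10L
  noise <- stats::rnorm(n_int, 0, params$rri_noise_sd_ms *
                          sqrt(1 - params$ar1_coeff^2))
  if (params$ar1_coeff > 0) {
    noise <- as.numeric(stats::filter(noise, params$ar1_coeff,
                                      method = "recursive"))
  }
  r <- params$baseline_rri_ms + noise
  if (params$diurnal_drift_ms > 0) {
    t_approx <- start_ms + cumsum(r) - r
    hour <- (t_approx / MS_PER_HOUR) %% 24
    r <- r + params$diurnal_drift_ms * cos(2 * pi * (hour - 4) / 24)
  }
  if (any(r <= 0)) {
    stop("parameters produced a non-positive RR interval", call. = FALSE)
  }
  tb <- start_ms + c(0, cumsum(r))          # beats; interval j starts at tb[j]
  if (length(onsets)) {
    ord <- order(onsets)
    shift <- 0
    kresp <- params$response_len_beats
    for (e in ord) {
      if (outcomes[e] == "none") next
      o <- onsets[e] - shift
      idx <- findInterval(o, tb)
      j0 <- if (idx >= 1 && tb[idx] == o) idx else idx + 1L
      if (j0 < 1 || j0 + kresp - 1L > length(r)) next
      s <- if (outcomes[e] == "acc") -params$response_delta_ms
           else params$response_delta_ms
      r[j0:(j0 + kresp - 1L)] <- r[j0:(j0 + kresp - 1L)] + s
      shift <- shift + kresp * s
    }
    if (any(r <= 0)) {
      stop("injected responses produced a non-positive RR interval",
           call. = FALSE)
    }
    tb <- start_ms + c(0, cumsum(r))
  }
  tb[tb <= end_ms]
}

#' Missingness scenarios
#'
#' Describes the trial's attrition pattern: participants whose Period-1
#' recording was lost to equipment failure, participants who withdrew after
#' Period 1 (no Period-2 data at all), and scattered Period-2
#' participant x sound cells lost to clerical error (the imputation
#' targets). A withdrawn participant cannot also have missing Period-2
#' cells.
#'
#' @param machine_failure_period1,withdrawals_after_period1 Character ids.
#' @param missing_period2_cells Tibble `participant_id`, `sound_code`.
#' @return A list of class `missingness_scenario`.
#' @export
missingness_scenario <- function(machine_failure_period1 = character(),
                                 withdrawals_after_period1 = character(),
                                 missing_period2_cells =
                                   tibble::tibble(participant_id = character(),
                                                  sound_code = character())) {
  overlap <- intersect(withdrawals_after_period1,
                       missing_period2_cells$participant_id)
  if (length(overlap)) {
    stop("withdrawn participants cannot have Period-2 cells: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(
    machine_failure_period1 = machine_failure_period1,
    withdrawals_after_period1 = withdrawals_after_period1,
    missing_period2_cells = missing_period2_cells
  ), class = "missingness_scenario")
}

#' Trial-profile missingness
#'
#' Reproduces the attrition arithmetic of the study profile: two withdrawals
#' from each group after Period 1 (leaving 18 with Period-2 data), Period-1
#' equipment failures chosen among the remaining participants so that the
#' both-period crossover set splits 8 (Group 1) and 6 (Group 2), and
#' scattered missing Period-2 cells for two Group-2 completers (leaving a
#' per-protocol set of 16).
#'
#' @param groups Group assignment from [randomize_groups()].
#' @param target_both Desired (Group 1, Group 2) both-period counts.
#' @param n_withdraw Withdrawals per group after Period 1.
#' @param n_missing_cell_participants Participants with missing Period-2
#'   cells (taken from the larger both-period group's complement — Group 2
#'   in the study profile).
#' @param n_missing_cells_each Sounds lost per affected participant.
#' @return A `missingness_scenario`.
#' @export
trial_profile_scenario <- function(groups, target_both = c(8L, 6L),
                                       n_withdraw = c(2L, 2L),
                                       n_missing_cell_participants = 2L,
                                       n_missing_cells_each = 4L) {
  by_grp <- split(groups$participant_id, groups$group)
  wd <- unlist(purrr::map2(by_grp, n_withdraw, function(ids, k) {
    sample(ids, k)
  }), use.names = FALSE)
  remaining <- purrr::map(by_grp, setdiff, y = wd)
  n_fail <- purrr::map2_int(remaining, target_both,
                            function(ids, t) length(ids) - t)
  if (any(n_fail < 0)) {
    stop("group sizes too small for the requested both-period targets",
         call. = FALSE)
  }
  mf <- unlist(purrr::map2(remaining, n_fail, function(ids, k) {
    sample(ids, k)
  }), use.names = FALSE)
  # missing cells hit Group-2 both-period completers, as in the study profile
  pool <- setdiff(remaining[["2"]], mf)
  miss_ids <- sample(pool, min(n_missing_cell_participants, length(pool)))
  cells <- purrr::map_dfr(miss_ids, function(id) {
    tibble::tibble(participant_id = id,
                   sound_code = sample(sound_codes(), n_missing_cells_each))
  })
  missingness_scenario(machine_failure_period1 = mf,
                       withdrawals_after_period1 = wd,
                       missing_period2_cells = cells)
}

#' Apply a missingness scenario to a simulated dataset
#'
#' Drops Period-1 beats and events for equipment-failure participants,
#' all Period-2 data for withdrawn participants, and the named Period-2
#' participant x sound events (so their presentations are never scored),
#' then derives the analysis populations: ITT = any Period-2 data,
#' PPS = ITT completers without missing cells.
#'
#' @param data List with `beats`, `events`, `groups` (as from
#'   [simulate_experiment()]).
#' @param scenario A [missingness_scenario()].
#' @return The reduced list, plus `populations` (tibble `participant_id`,
#'   `group`, `itt`, `pps`) and `scenario`.
#' @export
apply_missingness <- function(data, scenario) {
  stopifnot(inherits(scenario, "missingness_scenario"))
  ids <- data$groups$participant_id
  unknown <- setdiff(c(scenario$machine_failure_period1,
                       scenario$withdrawals_after_period1,
                       scenario$missing_period2_cells$participant_id), ids)
  if (length(unknown)) {
    stop("unknown participant id(s) in scenario: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop_beats <- with(data$beats,
    (participant_id %in% scenario$machine_failure_period1 & period == 1) |
    (participant_id %in% scenario$withdrawals_after_period1 & period == 2))
  drop_events <- with(data$events,
    (participant_id %in% scenario$machine_failure_period1 & period == 1) |
    (participant_id %in% scenario$withdrawals_after_period1 & period == 2))
  cells <- scenario$missing_period2_cells
  if (nrow(cells)) {
    key <- paste(data$events$participant_id, data$events$sound_code)
    drop_events <- drop_events |
      (data$events$period == 2 & key %in% paste(cells$participant_id,
                                                cells$sound_code))
  }
  data$beats <- data$beats[!drop_beats, ]
  data$events <- data$events[!drop_events, ]
  itt <- !(ids %in% scenario$withdrawals_after_period1)
  data$populations <- tibble::tibble(
    participant_id = ids, group = data$groups$group, itt = itt,
    pps = itt & !(ids %in% cells$participant_id)
  )
  data$scenario <- scenario
  data
}

#' Simulate a complete synthetic experiment
#'
#' One call producing everything the pipeline consumes: block
#' randomization, the two-period stimulus schedule, RR-interval streams with
#' injected responses, and (optionally) the trial-profile missingness. All
#' randomness flows from `seed`.
#'
#' @param params A [simulation_params()].
#' @param layout An [experiment_layout()].
#' @param scenario `"none"`, `"trial_profile"` (trial-profile attrition), or a
#'   [missingness_scenario()].
#' @param seed Integer seed.
#' @return A list: `beats`, `events` (with the `injected` outcome column),
#'   `groups`, `populations`, `scenario`, `params`, `layout`.
#' @export
simulate_experiment <- function(params = simulation_params(),
                                layout = experiment_layout(),
                                scenario = "trial_profile", seed = 1L) {
  set.seed(seed)
  groups <- randomize_groups(params$n_participants, params$block_sizes)
  events <- build_schedule(groups, layout)
  beats <- simulate_beats(events, params, layout)
  events$injected <- attr(beats, "outcomes")$injected
  attr(beats, "outcomes") <- NULL
  data <- list(beats = beats, events = events, groups = groups,
               params = params, layout = layout)
  if (inherits(scenario, "missingness_scenario")) {
    data <- apply_missingness(data, scenario)
  } else if (identical(scenario, "trial_profile")) {
    data <- apply_missingness(data, trial_profile_scenario(groups))
  } else if (!identical(scenario, "none")) {
    stop("scenario must be 'none', 'trial_profile', or a missingness_scenario",
         call. = FALSE)
  }
  if (is.null(data$populations)) {
    data$populations <- tibble::tibble(
      participant_id = groups$participant_id, group = groups$group,
      itt = TRUE, pps = TRUE
    )
  }
  data
}
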