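test_that("block randomization assigns near-balanced groups in even blocks", {
  set.seed(41)
  g <- randomize_groups(22)
  expect_equal(nrow(g), 22)
  expect_true(all(g$group %in% 1:2))
  expect_lte(abs(sum(g$group == 1) - sum(g$group == 2)), 4)  # truncated block
  # each complete block is balanced: any prefix imbalance is bounded
  run_imbalance <- cumsum(ifelse(g$group == 1, 1, -1))
  expect_lte(max(abs(run_imbalance)), 3)
})

test_that("schedules present each sound once per stimulus hour with bounded gaps", {
  set.seed(42)
  groups <- tibble::tibble(participant_id = c("p01", "p02"), group = 1:2)
  ev <- build_schedule(groups, periods = 1)
  lay <- experiment_layout()

  # participant on A/D: 14 hours x 16 sounds; on B/C: 13 physical hours
  n1 <- dplyr::count(ev, participant_id)
  expect_setequal(n1$n, c(14 * 16, 13 * 16))
  per_sound <- ev |> dplyr::count(participant_id, sound_code)
  expect_true(all(per_sound$n %in% c(13, 14)))

  # each sound exactly once per hour
  per_hour <- ev |>
    dplyr::mutate(hour = floor(onset_ms / 3.6e6)) |>
    dplyr::count(participant_id, hour, sound_code)
  expect_true(all(per_hour$n == 1))

  # bathing hour holds no presentations
  bath_h <- (24 + 21)
  expect_false(any(floor(ev$onset_ms / 3.6e6) == bath_h))

  # within-hour inter-onset gaps stay inside [195, 255] s
  gaps <- ev |>
    dplyr::mutate(hour = floor(onset_ms / 3.6e6)) |>
    dplyr::group_by(participant_id, hour) |>
    dplyr::arrange(onset_ms, .by_group = TRUE) |>
    dplyr::summarise(g = list(diff(onset_ms) / 1000), .groups = "drop") |>
    dplyr::pull(g) |> unlist()
  expect_true(all(gaps >= 195 & gaps <= 255))

  # onsets lie inside their segment windows (reader validates silently)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  expect_no_warning(read_events(f))
})

test_that("infeasible hours are rejected", {
  lay <- experiment_layout(inter_onset_mean_s = 300, inter_onset_halfwidth_s = 10)
  groups <- tibble::tibble(participant_id = "p01", group = 1)
  expect_error(build_schedule(groups, lay, periods = 1), "infeasible")
})

test_that("simulation is reproducible under a fixed seed", {
  p <- simulation_params(n_participants = 3)
  a <- simulate_experiment(p, scenario = "none", seed = 7)
  b <- simulate_experiment(p, scenario = "none", seed = 7)
  expect_identical(a$beats$t_ms, b$beats$t_ms)
  expect_identical(a$events, b$events)
  c_ <- simulate_experiment(p, scenario = "none", seed = 8)
  expect_false(identical(a$beats$t_ms, c_$beats$t_ms))
})

test_that("injected responses land on the scored post window with the right sign", {
  # overwhelming acceleration on every presentation
  p <- simulation_params(n_participants = 2, p_acc = 1, p_dec = 0,
                         response_delta_ms = 250)
  s <- simulate_experiment(p, scenario = "none", seed = 9)
  or_tbl <- score_events(s$beats, s$events)
  valid <- dplyr::filter(or_tbl, label != "invalid")
  expect_gt(nrow(valid), 0)
  expect_true(all(valid$label == "acceleration"))

  # pure deceleration mirrors the sign
  pd <- simulation_params(n_participants = 2, p_acc = 0, p_dec = 1,
                          response_delta_ms = 250)
  sd_ <- simulate_experiment(pd, scenario = "none", seed = 9)
  ord <- score_events(sd_$beats, sd_$events)
  expect_true(all(ord$label[ord$label != "invalid"] == "deceleration"))
})

test_that("scored outcomes match the injected outcome labels event by event", {
  s <- small_sim()   # p_acc = p_dec = 0.15, delta 250 (overwhelming)
  or_tbl <- small_scored()
  valid <- !is.na(or_tbl$or_value)
  inj <- s$events$injected[valid]
  lab <- or_tbl$label[valid]
  expect_true(all(lab[inj == "acc"] == "acceleration"))
  expect_true(all(lab[inj == "dec"] == "deceleration"))
  # uninjected events are salient only at the null rate
  null_rate <- mean(lab[inj == "none"] != "unnoticed")
  expect_lt(null_rate, 0.06)
})

test_that("sleep windows hold no beats and block windows across them", {
  s <- small_sim()
  hour <- (s$beats$t_ms / 3.6e6) %% 24
  expect_false(any(hour > 23.5 | hour < 7.5))
})

test_that("the trial-profile missingness reproduces the published attrition counts", {
  set.seed(43)
  groups <- randomize_groups(22)
  sc <- trial_profile_scenario(groups)
  expect_length(sc$withdrawals_after_period1, 4)
  expect_length(sc$machine_failure_period1, 4)
  expect_equal(length(unique(sc$missing_period2_cells$participant_id)), 2)

  n_remaining <- table(groups$group) - c(2, 2)
  expect_equal(length(sc$machine_failure_period1),
               sum(n_remaining - c(8, 6)))

  # end to end: the scenario is rebuilt against the simulated assignment
  p <- simulation_params(n_participants = 22)
  s <- simulate_experiment(p, scenario = "trial_profile", seed = 44)
  expect_equal(sum(s$populations$itt), 18)
  expect_equal(sum(s$populations$pps), 16)
  # both-period completers split 8 / 6 across groups
  both <- s$events |>
    dplyr::distinct(participant_id, period) |>
    dplyr::count(participant_id) |>
    dplyr::filter(n == 2) |>
    dplyr::inner_join(s$groups, by = "participant_id")
  expect_equal(as.integer(table(both$group)), c(8L, 6L))
})

test_that("missingness application validates ids and handles the empty scenario", {
  p <- simulation_params(n_participants = 3)
  s <- simulate_experiment(p, scenario = "none", seed = 45)
  empty <- missingness_scenario()
  s2 <- apply_missingness(s, empty)
  expect_equal(nrow(s2$beats), nrow(s$beats))
  expect_equal(nrow(s2$events), nrow(s$events))

  bad <- missingness_scenario(withdrawals_after_period1 = "p99")
  expect_error(apply_missingness(s, bad), "unknown participant")

  # a withdrawn participant cannot also carry missing period-2 cells
  expect_error(missingness_scenario(
    withdrawals_after_period1 = "p01",
    missing_period2_cells = tibble::tibble(participant_id = "p01",
                                           sound_code = "M01")
  ), "cannot have")

  # withdrawing everyone leaves an empty ITT population downstream
  all_wd <- missingness_scenario(
    withdrawals_after_period1 = s$groups$participant_id)
  s3 <- apply_missingness(s, all_wd)
  or3 <- score_events(s3$beats, dplyr::filter(s3$events, period == 2))
  expect_error(run_rct(or3, "M01", s3$populations), "empty ITT")
})

test_that("parameters that could produce non-positive intervals are rejected", {
  expect_error(
    simulate_beats(small_sim()$events,
                   simulation_params(baseline_rri_ms = 300,
                                     response_delta_ms = 250)),
    "non-positive"
  )
})
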