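test_that("window extraction takes the last/first five intervals around the onset", {
  # 800 ms spacing up to t = 4000, then 760 ms spacing
  b <- derive_rri(tibble::tibble(
    participant_id = "p01",
    t_ms = c(seq(-1600, 4000, by = 800), 4000 + 760 * (1:6))
  ))
  w <- extract_window_pair(b, onset_ms = 4000)
  expect_true(w$complete)
  expect_equal(w$pre_rri_ms, rep(800, 5))
  expect_equal(w$post_rri_ms, rep(760, 5))
})

test_that("the interval straddling the onset belongs to neither window", {
  b <- derive_rri(tibble::tibble(
    participant_id = "p01",
    t_ms = c(seq(-1600, 3200, by = 800), 4000, 4000 + 760 * (1:6))
  ))
  # onset strictly inside (3200, 4000): that 800 ms interval is excluded;
  # pre ends at 3200, post starts at 4000
  w <- extract_window_pair(b, onset_ms = 3600)
  expect_true(w$complete)
  expect_equal(w$pre_rri_ms, rep(800, 5))
  expect_equal(w$post_rri_ms, rep(760, 5))
})

test_that("boundary ties are deterministic: ending-at-onset is pre, starting-at-onset is post", {
  b <- derive_rri(tibble::tibble(
    participant_id = "p01",
    t_ms = c(seq(-2400, 3200, by = 800), 3200 + 760 * (1:6))
  ))
  w <- extract_window_pair(b, onset_ms = 3200)  # onset exactly on a beat
  expect_true(w$complete)
  expect_equal(w$pre_rri_ms, rep(800, 5))   # interval ending at 3200 included
  expect_equal(w$post_rri_ms, rep(760, 5))  # interval starting at 3200 included
})

test_that("insufficient context or recording gaps yield incomplete pairs, not errors", {
  b <- grid_beats(t0 = 0, n = 30, rri = 800)
  expect_false(extract_window_pair(b, onset_ms = 2000)$complete)  # 2 pre intervals
  expect_false(extract_window_pair(b, onset_ms = -100)$complete)  # before record
  expect_false(extract_window_pair(b, onset_ms = 1e9)$complete)   # after record
  # a window spanning more than max_span_ms is rejected
  gap <- derive_rri(tibble::tibble(
    participant_id = "p01",
    t_ms = c(0:5 * 800, 50000 + 0:5 * 800)
  ))
  expect_false(extract_window_pair(gap, onset_ms = 50000,
                                   max_span_ms = 15000)$complete)
})

test_that("compute_or reproduces the hand-computed example and guards degeneracy", {
  pre <- c(800, 810, 790, 805, 795)
  post <- c(760, 765, 770, 755, 750)
  pair <- structure(list(pre_rri_ms = pre, post_rri_ms = post, onset_ms = 0,
                         complete = TRUE, valid = TRUE), class = "window_pair")
  m <- compute_or(pair)
  expect_equal(m$m1_ms, 800)
  expect_equal(m$m2_ms, 760)
  expect_equal(m$sd_ms, 7.90569415042095, tolerance = 1e-12)
  expect_equal(m$or_value, 5.05964425626941, tolerance = 1e-12)
  expect_equal(m$label, "acceleration")

  same <- structure(list(pre_rri_ms = pre, post_rri_ms = pre, onset_ms = 0,
                         complete = TRUE, valid = TRUE), class = "window_pair")
  expect_equal(compute_or(same)$or_value, 0)
  expect_equal(compute_or(same)$label, "unnoticed")

  flat <- structure(list(pre_rri_ms = rep(800, 5), post_rri_ms = post,
                         onset_ms = 0, complete = TRUE, valid = TRUE),
                    class = "window_pair")
  expect_equal(compute_or(flat)$label, "invalid")
  expect_true(is.na(compute_or(flat)$or_value))
})

test_that("classification thresholds are strict inequalities", {
  mk <- function(or) {
    # pre window with exact mean 1000 and exact sample SD 2, so the OR value
    # is exactly `or` in floating point
    structure(list(pre_rri_ms = 1000 + c(-2, -2, 0, 2, 2),
                   post_rri_ms = rep(1000 - 2 * or, 5),
                   onset_ms = 0, complete = TRUE, valid = TRUE),
              class = "window_pair")
  }
  expect_equal(compute_or(mk(2))$label, "unnoticed")    # |OR| exactly 2
  expect_equal(compute_or(mk(-2))$label, "unnoticed")
  expect_equal(compute_or(mk(2 + 1e-9))$label, "acceleration")
  expect_equal(compute_or(mk(-2 - 1e-9))$label, "deceleration")
})

test_that("OR is invariant to RRI shift and positive scaling, with the stated sign convention", {
  set.seed(11)
  for (i in 1:50) {
    pre <- rnorm(5, 850, 30)
    post <- rnorm(5, 850, 30)
    mk <- function(a, b) structure(
      list(pre_rri_ms = a, post_rri_ms = b, onset_ms = 0,
           complete = TRUE, valid = TRUE), class = "window_pair")
    base <- compute_or(mk(pre, post))$or_value
    expect_equal(compute_or(mk(pre + 123, post + 123))$or_value, base,
                 tolerance = 1e-9)
    expect_equal(compute_or(mk(pre * 3.7, post * 3.7))$or_value, base,
                 tolerance = 1e-9)
  }
  # shortened post intervals (heart speeds up) give positive OR
  fast <- structure(list(pre_rri_ms = c(800, 810, 790, 805, 795),
                         post_rri_ms = rep(700, 5), onset_ms = 0,
                         complete = TRUE, valid = TRUE), class = "window_pair")
  expect_gt(compute_or(fast)$or_value, 0)
})

test_that("score_events returns one row per event in order, flags artifacts and gaps", {
  b <- grid_beats(t0 = 0, n = 200, rri = 800)
  ev <- tibble::tibble(participant_id = "p01",
                       sound_code = rep(c("M01", "C16"), 3),
                       onset_ms = c(50000, 20000, 80000, 100000, 110000, 130000),
                       segment = "A", period = 1L)
  out <- score_events(b, ev)
  expect_equal(nrow(out), 6)
  expect_equal(out$onset_ms, ev$onset_ms)  # event order preserved
  expect_equal(nrow(score_events(b, ev[0, ])), 0)

  # an implausible interval inside a window invalidates the measurement
  b2 <- b
  b2$t_ms[64:200] <- b2$t_ms[64:200] + 1500   # one 2300 ms interval at beat 63
  b2 <- derive_rri(b2)
  out2 <- score_events(b2, tibble::tibble(
    participant_id = "p01", sound_code = "M01",
    onset_ms = b2$t_ms[65] + 10, segment = "A", period = 1L))
  expect_equal(out2$label, "invalid")
})

test_that("score_events agrees with per-event extraction plus compute_or", {
  or_tbl <- small_scored()
  s <- small_sim()
  set.seed(5)
  rows <- sample(nrow(or_tbl), 25)
  for (i in rows) {
    ev <- or_tbl[i, ]
    b <- dplyr::filter(s$beats, participant_id == ev$participant_id,
                       period == ev$period)
    m <- compute_or(extract_window_pair(b, ev$onset_ms))
    expect_equal(m$label, ev$label)
    if (!is.na(ev$or_value)) {
      expect_equal(m$or_value, ev$or_value, tolerance = 1e-12)
    }
  }
})
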