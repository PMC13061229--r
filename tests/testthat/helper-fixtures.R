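# shared fixtures and independent oracles, built in code at test time

# beats on a regular grid: first beat at t0, n beats spaced rri apart
grid_beats <- function(t0 = 0, n = 30, rri = 800, id = "p01") {
  derive_rri(tibble::tibble(participant_id = id,
                            t_ms = t0 + (seq_len(n) - 1) * rri))
}

# naive re-implementation of the OR statistic: explicit formulas, no shared
# code (base mean() keeps the means bit-identical so the pre-minus-post
# cancellation does not limit the comparison tolerance)
or_naive <- function(pre, post) {
  k <- length(pre)
  m1 <- mean(pre)
  m2 <- mean(post)
  ssq <- 0
  for (x in pre) ssq <- ssq + (x - m1)^2
  sdv <- sqrt(ssq / (k - 1))
  (m1 - m2) / sdv
}

# Welch test from first principles (formulas written out, cross-check route)
welch_naive <- function(g1, g2, conf_level = 0.95) {
  n1 <- length(g1); n2 <- length(g2)
  v1 <- sum((g1 - mean(g1))^2) / (n1 - 1)
  v2 <- sum((g2 - mean(g2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(g2) - mean(g1)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(t = t, df = df, p = p,
       ci = (mean(g2) - mean(g1)) + c(-1, 1) * q * sqrt(se2))
}

# one-way ANOVA from sums of squares only
anova_naive <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, df_between = dfb, df_within = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       eta_sq = ssb / (ssb + ssw))
}

# a small simulated experiment, shared across test files (built once)
.shared <- new.env()
small_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_experiment(
      simulation_params(n_participants = 6), scenario = "none", seed = 101
    )
  }
  .shared$sim
}
small_scored <- function() {
  if (is.null(.shared$or)) {
    s <- small_sim()
    .shared$or <- score_events(s$beats, s$events)
  }
  .shared$or
}

# printed crossover screening inputs: per-sound two-tailed p-values of the
# published carryover and period-effect Welch tables
printed_carryover_p <- c(
  M01 = 0.825, M02 = 0.843, M03 = 0.365, M04 = 0.705, M05 = 0.039,
  M06 = 0.358, M07 = 0.409, M08 = 0.727, C09 = 0.041, C10 = 0.487,
  C11 = 0.010, C12 = 0.629, C13 = 0.535, C14 = 0.819, C15 = 0.126,
  C16 = 0.780
)
printed_period_p <- c(
  M01 = 0.622, M02 = 0.148, M03 = 0.263, M04 = 0.137, M05 = 0.157,
  M06 = 0.466, M07 = 0.400, M08 = 0.237, C09 = 0.278, C10 = 0.008,
  C11 = 0.447, C12 = 0.135, C13 = 0.296, C14 = 0.531, C15 = 0.021,
  C16 = 0.099
)
published_retained <- c("M01", "M02", "M03", "M04", "M06", "M07", "M08",
                        "C12", "C13", "C14", "C16")
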