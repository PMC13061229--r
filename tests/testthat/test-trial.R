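test_that("median imputation fills missing cells from the participant's own period-2 values", {
  app <- tibble::tibble(
    participant_id = "p01",
    sound_code = c("M01", "M02", "M03", "M04"),
    apparency_pct = c(0, 14.286, 28.571, NA)
  )
  out <- impute_period2_median(app)
  expect_equal(out$data$apparency_pct[out$data$sound_code == "M04"], 14.286)
  expect_equal(nrow(out$log), 1)
  expect_equal(out$log$imputed_value, 14.286)

  # even count: midpoint convention
  app2 <- tibble::tibble(participant_id = "p01",
                         sound_code = c("M01", "M02", "M03"),
                         apparency_pct = c(0, 28.571, NA))
  expect_equal(impute_period2_median(app2)$data$apparency_pct[3], 14.2855)

  # absent grid cells are also imputed
  app3 <- tibble::tibble(participant_id = "p01", sound_code = "M01",
                         apparency_pct = 20)
  out3 <- impute_period2_median(app3, sounds = c("M01", "M02"))
  expect_equal(out3$data$apparency_pct, c(20, 20))

  # no missing -> identity, empty log
  full <- tibble::tibble(participant_id = "p01",
                         sound_code = c("M01", "M02"),
                         apparency_pct = c(10, 20))
  outf <- impute_period2_median(full)
  expect_equal(outf$data$apparency_pct, full$apparency_pct)
  expect_equal(nrow(outf$log), 0)

  # a participant with nothing to impute from is an error
  none <- tibble::tibble(participant_id = c("p01", "p02"),
                         sound_code = "M01", apparency_pct = c(10, NA))
  expect_error(impute_period2_median(none), "cannot impute.*p02")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares and df shapes", {
  d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
  a <- anova_oneway(d, y, g)
  expect_equal(a$f, 8)                       # SSB = 4, SSW = 1
  expect_equal(c(a$df_between, a$df_within), c(1L, 2L))
  expect_equal(a$eta_sq, 0.8)

  # equal group means with within-group spread -> F = 0, eta^2 = 0
  d0 <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 3, 2, 1))
  a0 <- anova_oneway(d0, y, g)
  expect_equal(a0$f, 0)
  expect_equal(a0$eta_sq, 0)

  # an 18 x 11 grid gives the (10, 187) shape; 16 x 11 gives (10, 165)
  set.seed(31)
  g18 <- tidyr::expand_grid(id = 1:18, sound = sprintf("s%02d", 1:11)) |>
    dplyr::mutate(y = rnorm(dplyr::n()))
  a18 <- anova_oneway(g18, y, sound)
  expect_equal(c(a18$df_between, a18$df_within), c(10L, 187L))
  a16 <- anova_oneway(dplyr::filter(g18, id <= 16), y, sound)
  expect_equal(c(a16$df_between, a16$df_within), c(10L, 165L))

  # degenerate: all observations identical
  dz <- data.frame(g = rep(c("a", "b"), each = 2), y = rep(5, 4))
  expect_true(anova_oneway(dz, y, g)$degenerate)
})

test_that("ANOVA agrees with the sums-of-squares oracle and the eta/F identity", {
  set.seed(32)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    n_per <- sample(2:10, k, replace = TRUE)
    g <- rep(seq_len(k), n_per)
    y <- rnorm(length(g), mean = g * runif(1, 0, 0.5))
    a <- anova_oneway(data.frame(g = g, y = y), y, g)
    ref <- anova_naive(y, g)
    expect_equal(a$f, ref$f, tolerance = 1e-10)
    expect_equal(a$p, ref$p, tolerance = 1e-10)
    expect_equal(a$eta_sq, ref$eta_sq, tolerance = 1e-10)
    # eta^2 = F dfb / (F dfb + dfw), algebraically
    expect_equal(a$eta_sq,
                 a$f * a$df_between / (a$f * a$df_between + a$df_within),
                 tolerance = 1e-12)
    expect_true(a$eta_sq >= 0 && a$eta_sq <= 1)
  }
})

test_that("paired t matches its definition, antisymmetry and the d_z identity", {
  x <- c(10, 12, 9, 14, 11)
  same <- paired_t(x, x)
  expect_equal(c(same$t, same$p, same$d), c(0, 1, 0))

  set.seed(33)
  day <- rnorm(18, 30, 10); eve <- rnorm(18, 35, 10)
  a <- paired_t(day, eve)
  b <- paired_t(eve, day)
  expect_equal(b$t, -a$t, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_equal(b$d, a$d, tolerance = 1e-12)
  expect_equal(a$d, abs(a$t) / sqrt(18), tolerance = 1e-12)
  expect_equal(a$df, 17L)
  # hand formula: t = mean(diff) / (sd(diff)/sqrt(n))
  expect_equal(a$t, mean(day - eve) / (sd(day - eve) / sqrt(18)),
               tolerance = 1e-12)

  # constant non-zero difference -> degenerate
  expect_true(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))$degenerate)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(34)
  p <- replicate(400, {
    g <- tidyr::expand_grid(id = 1:18, sound = sprintf("s%02d", 1:11))
    anova_oneway(dplyr::mutate(g, y = rnorm(dplyr::n())), y, sound)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("run_rct assembles ITT/PPS ANOVAs, diurnal tests and ratios", {
  or_tbl <- small_scored()
  s <- small_sim()
  m2 <- dplyr::filter(or_tbl, period == 2)
  retained <- unique(m2$sound_code)[1:5]
  res <- run_rct(m2, retained, s$populations)
  expect_s3_class(res, "apparency_rct")
  expect_equal(res$itt_anova$df_between, 4L)
  expect_equal(res$itt_anova$n, 6 * 5)
  expect_equal(nrow(res$diurnal), 5)
  expect_equal(sort(res$ratios$sound_code), sort(retained))
  expect_equal(res$ratios$acc_pct + res$ratios$dec_pct +
                 res$ratios$unnoticed_pct, rep(100, 5))
  expect_equal(nrow(glance(res)), 2)
  expect_equal(tidy(res), res$diurnal)

  expect_error(run_rct(m2, character(), s$populations), "empty")
  expect_error(run_rct(or_tbl, retained, s$populations), "single period")
})
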