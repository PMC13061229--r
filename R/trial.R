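#' Median imputation of missing Period-2 apparency cells
#'
#' For the intention-to-treat population, a participant's missing
#' participant x sound apparency cells are filled with the median of that
#' same participant's available Period-2 sound-level apparencies — the
#' imputation never borrows information from Period 1 or from other
#' participants. A participant with no available Period-2 observation cannot
#' be imputed and is an error.
#'
#' @param apparency_records Period-2 apparency tibble (`participant_id`,
#'   `sound_code`, `apparency_pct`, possibly with `NA` cells).
#' @param participants Participants the completed grid must cover (default:
#'   those present in the records).
#' @param sounds Sound codes the grid must cover (default: those present).
#' @return A list: `data` (completed tibble with an `imputed` flag) and
#'   `log` (tibble of every imputed cell with the value used).
#' @export
impute_period2_median <- function(apparency_records, participants = NULL,
                                  sounds = NULL) {
  if (is.null(participants)) {
    participants <- unique(apparency_records$participant_id)
  }
  if (is.null(sounds)) sounds <- unique(apparency_records$sound_code)
  grid <- tidyr::expand_grid(participant_id = participants,
                             sound_code = sounds)
  dat <- dplyr::left_join(
    grid,
    apparency_records[, c("participant_id", "sound_code", "apparency_pct")],
    by = c("participant_id", "sound_code")
  )
  meds <- dat |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_avail = sum(!is.na(.data$apparency_pct)),
                     med = stats::median(.data$apparency_pct, na.rm = TRUE),
                     .groups = "drop")
  none <- meds$participant_id[meds$n_avail == 0]
  if (length(none)) {
    stop("cannot impute: no available Period-2 observations for ",
         paste(none, collapse = ", "), call. = FALSE)
  }
  dat <- dplyr::left_join(dat, meds[, c("participant_id", "med")],
                          by = "participant_id")
  dat$imputed <- is.na(dat$apparency_pct)
  log <- dat[dat$imputed, c("participant_id", "sound_code", "med")]
  names(log)[3] <- "imputed_value"
  dat$apparency_pct[dat$imputed] <- dat$med[dat$imputed]
  dat$med <- NULL
  list(data = tibble::as_tibble(dat), log = tibble::as_tibble(log))
}

#' One-way fixed-effects ANOVA with eta-squared
#'
#' Classical one-way ANOVA comparing apparency across sounds, treating each
#' participant x sound value as one observation in its sound's group, with
#' eta-squared (between-group over total sum of squares) as effect size.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-select: bare names or strings) holding
#'   the response and the grouping factor.
#' @return An object of class `apparency_anova` with fields `f`,
#'   `df_between`, `df_within`, `p`, `eta_sq`, `degenerate`; supports
#'   `tidy()` and `glance()`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
#' anova_oneway(d, y, g)  # F = 8, df = (1, 2), eta^2 = 0.8
#' @export
anova_oneway <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2), !anyNA(y))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    res <- list(f = NA_real_, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g), p = NA_real_,
                eta_sq = NA_real_, degenerate = TRUE, n = length(y),
                k = nlevels(g))
    return(structure(res, class = "apparency_anova"))
  }
  fit <- stats::aov(y ~ g)
  tab <- stats::anova(fit)
  ssb <- tab$`Sum Sq`[1]
  res <- list(
    f = tab$`F value`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    p = tab$`Pr(>F)`[1],
    eta_sq = ssb / sst,
    degenerate = FALSE,
    n = length(y),
    k = nlevels(g)
  )
  structure(res, class = "apparency_anova")
}

#' @export
print.apparency_anova <- function(x, ...) {
  if (x$degenerate) {
    cat("<one-way ANOVA> degenerate (zero total variance),",
        sprintf("df = (%d, %d)\n", x$df_between, x$df_within))
  } else {
    cat(sprintf("<one-way ANOVA> F(%d, %d) = %.3f, p = %.3f, eta^2 = %.3f\n",
                x$df_between, x$df_within, x$f, x$p, x$eta_sq))
  }
  invisible(x)
}

#' @method tidy apparency_anova
#' @export
tidy.apparency_anova <- function(x, ...) {
  tibble::tibble(term = "group", statistic = x$f, df = x$df_between,
                 df_residual = x$df_within, p.value = x$p, eta_sq = x$eta_sq)
}

#' @method glance apparency_anova
#' @export
glance.apparency_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, df = x$df_between,
                 df_residual = x$df_within, p.value = x$p, eta_sq = x$eta_sq,
                 nobs = x$n, n_groups = x$k, degenerate = x$degenerate)
}

#' Paired t-test with Cohen's d_z
#'
#' Two-tailed paired t-test on per-participant differences
#' `day - evening`, with the within-subject effect size
#' `d_z = |mean(diff)| / sd(diff) = |t| / sqrt(n)`. The between-condition
#' pooled-SD variant of d is deliberately not used: the design is paired.
#' A zero-variance difference vector is flagged degenerate.
#'
#' @param day,evening Equal-length paired numeric vectors.
#' @return A one-row tibble: `n`, `mean_diff`, `t`, `df`, `p`, `d`,
#'   `degenerate`.
#' @export
paired_t <- function(day, evening) {
  stopifnot(length(day) == length(evening), length(day) >= 2,
            !anyNA(day), !anyNA(evening))
  n <- length(day)
  diff <- day - evening
  if (stats::sd(diff) == 0) {
    if (all(diff == 0)) {
      return(tibble::tibble(n = n, mean_diff = 0, t = 0, df = n - 1L, p = 1,
                            d = 0, degenerate = FALSE))
    }
    return(tibble::tibble(n = n, mean_diff = mean(diff), t = NA_real_,
                          df = n - 1L, p = NA_real_, d = NA_real_,
                          degenerate = TRUE))
  }
  ht <- stats::t.test(day, evening, paired = TRUE)
  tibble::tibble(n = n, mean_diff = mean(diff), t = unname(ht$statistic),
                 df = as.integer(ht$parameter), p = ht$p.value,
                 d = abs(unname(ht$statistic)) / sqrt(n), degenerate = FALSE)
}

#' Run the randomized-trial analyses on Period-2 measurements
#'
#' Produces the full second-period analysis bundle for the sounds retained
#' by the crossover screen:
#' \itemize{
#'   \item 14-hour apparency per participant x sound, with missing cells
#'     median-imputed per participant for the intention-to-treat (ITT)
#'     population and used as observed (no imputation) for the per-protocol
#'     set (PPS);
#'   \item one-way ANOVA across sounds with eta-squared, for both
#'     populations;
#'   \item per-sound daytime vs evening paired t-tests with Cohen's d_z on
#'     the ITT participants (pairwise exclusion of participants missing a
#'     daypart; diurnal cells are never imputed);
#'   \item pooled acceleration/deceleration/unnoticed response ratios.
#' }
#' The daytime - evening difference orientation means a negative t indicates
#' higher evening apparency; this convention is echoed in the result.
#'
#' @param measurements Scored Period-2 OR tibble (one period only).
#' @param retained_sounds Character vector from [screen_sounds()].
#' @param populations Tibble `participant_id`, `itt`, `pps` (logicals);
#'   population membership is input metadata, not inferred from the data.
#' @param ratio_sounds Sounds for the response-ratio table (default: the
#'   retained set).
#' @return An object of class `apparency_rct`: list with `itt_anova`,
#'   `pps_anova`, `diurnal`, `ratios`, `apparency_itt`, `apparency_pps`,
#'   `imputation_log`, `retained`, `note`.
#' @export
run_rct <- function(measurements, retained_sounds, populations,
                    ratio_sounds = NULL) {
  if (length(retained_sounds) == 0) {
    stop("retained sound list is empty: nothing to analyse", call. = FALSE)
  }
  if (length(unique(measurements$period)) > 1) {
    stop("run_rct expects measurements from a single period", call. = FALSE)
  }
  m <- dplyr::filter(measurements, .data$sound_code %in% retained_sounds)
  itt_ids <- populations$participant_id[populations$itt]
  pps_ids <- populations$participant_id[populations$pps]
  if (length(itt_ids) == 0) stop("empty ITT population", call. = FALSE)

  app <- suppressMessages(
    compute_apparency(dplyr::filter(m, .data$participant_id %in% itt_ids))
  )
  app <- dplyr::filter(app, !.data$undefined)
  imp <- impute_period2_median(app, participants = itt_ids,
                               sounds = retained_sounds)
  itt_anova <- anova_oneway(imp$data, "apparency_pct", "sound_code")

  app_pps <- dplyr::filter(app, .data$participant_id %in% pps_ids)
  pps_anova <- anova_oneway(app_pps, "apparency_pct", "sound_code")

  pairs <- suppressMessages(
    diurnal_split(dplyr::filter(m, .data$participant_id %in% itt_ids))
  )
  diurnal <- pairs |>
    dplyr::group_by(.data$sound_code) |>
    dplyr::group_modify(~ paired_t(.x$daytime_pct, .x$evening_pct)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$sound_code, sound_codes()))

  if (is.null(ratio_sounds)) ratio_sounds <- retained_sounds
  ratios <- response_ratios(
    dplyr::filter(m, .data$participant_id %in% itt_ids), sounds = ratio_sounds
  )

  structure(list(
    itt_anova = itt_anova, pps_anova = pps_anova, diurnal = diurnal,
    ratios = ratios, apparency_itt = imp$data, apparency_pps = app_pps,
    imputation_log = imp$log, retained = retained_sounds,
    note = "diurnal difference is daytime - evening; negative t = higher evening apparency"
  ), class = "apparency_rct")
}

#' @export
print.apparency_rct <- function(x, ...) {
  cat("<randomized-trial analysis>", length(x$retained), "retained sounds\n")
  cat("ITT: "); print(x$itt_anova)
  cat("PPS: "); print(x$pps_anova)
  sig <- dplyr::filter(x$diurnal, !is.na(.data$p), .data$p < 0.05)
  cat("diurnal paired tests:", nrow(x$diurnal), "sounds;",
      nrow(sig), "with p < 0.05",
      if (nrow(sig)) paste0("(", paste(sig$sound_code, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' @method tidy apparency_rct
#' @export
tidy.apparency_rct <- function(x, ...) x$diurnal

#' @method glance apparency_rct
#' @export
glance.apparency_rct <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$itt_anova), population = "ITT"),
    dplyr::mutate(glance(x$pps_anova), population = "PPS")
  ) |>
    dplyr::relocate("population")
}
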