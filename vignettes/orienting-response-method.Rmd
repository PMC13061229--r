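---
title: "Measuring auditory signal noticeability from heart-rate orienting responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory signal noticeability from heart-rate orienting responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(apparency)
library(dplyr)
```

## The problem

Alarms, chimes and notification sounds are designed to be noticed, but their
effectiveness is usually evaluated in quiet laboratories or by asking
listeners. Both approaches miss the setting that matters: everyday
environments with continuous background noise, where a signal must break
through without the listener attending to it. This package implements a
physiological alternative: detecting whether a sound was *noticed* from the
listener's own heartbeat.

When a salient, unexpected stimulus occurs, the autonomic nervous system
produces a reflexive *orienting response* (OR): heart rate transiently
accelerates (tension, surprise) or decelerates (calm attention). Both
directions indicate that the stimulus registered. On an electrocardiogram
this appears as a change in the RR intervals (RRIs) — the times between
successive heartbeats, in milliseconds — immediately after stimulus onset.

## The OR statistic

For each stimulus presentation the package takes the five RRIs ending at or
before the onset (the *pre* window) and the five beginning at or after it
(the *post* window). An interval that straddles the onset mixes pre- and
post-stimulus physiology and belongs to neither window. The statistic is

$$\mathrm{OR} = \frac{M_1 - M_2}{\mathrm{SD}},$$

where $M_1$ and $\mathrm{SD}$ are the mean and sample standard deviation
(divisor 4) of the pre-window intervals and $M_2$ is the mean of the
post-window intervals. Shortened post-stimulus intervals — faster heart
rate — give a positive OR. Classification uses strict thresholds:

* `acceleration` when $\mathrm{OR} > 2$,
* `deceleration` when $\mathrm{OR} < -2$,
* `unnoticed` otherwise,
* `invalid` when a window is incomplete, bridges a recording gap, contains
  a physiologically implausible interval, or has zero pre-window variance.

```{r}
pair <- extract_window_pair(
  derive_rri(tibble::tibble(
    participant_id = "p01",
    t_ms = c(0, 800, 1610, 2400, 3205, 4000, 4760, 5525, 6295, 7050, 7800)
  )),
  onset_ms = 4000
)
compute_or(pair)
```

### Why the threshold 2 is not arbitrary

Under the null hypothesis of no response — i.i.d. Gaussian RRIs — $M_1 -
M_2$ is a difference of two independent five-draw means and $\mathrm{SD}$
estimates the common scale on 4 degrees of freedom, so
$\mathrm{OR} = \sqrt{2/5}\, t_4$ exactly. The false-salience probability is
therefore available in closed form:

```{r}
2 * pt(-sqrt(10), df = 4)
```

About 3.4 % of null presentations are classified salient — a known,
analytically fixed contamination rate that the test suite verifies by Monte
Carlo and against the full simulation pipeline.

## Apparency

*Apparency* is the per-participant, per-sound salience score: 100 times the
number of salient presentations (either direction) over the number of valid
presentations. Invalid presentations leave numerator and denominator alike,
so equipment artifacts do not dilute the score. `compute_apparency()`
computes it for any extra grouping scope (period, segment, ...), and
`response_ratios()` reports the pooled acceleration / deceleration /
unnoticed split per sound, pooling raw counts so each row totals exactly
100 before rounding.

## The experimental protocol the simulator emulates

The reference protocol exposes each participant to 16 test sounds — 8
two-note piano chords ("musical" sounds M01–M08) and 8 matched pure-tone
pairs at the same frequencies ("complex" sounds C09–C16) — in a living-lab
apartment with recorded everyday background noise. Each experiment spans
three days:

* **Day 1** is adaptation: participants settle into the environment and no
  stimuli are scored. The simulator therefore omits Day 1 entirely — it
  contributes no measurements, only habituation, which the generator does
  not model.
* **Days 2 and 3** each contain a daytime segment (8:00–15:00) and an
  evening segment (16:00–23:00), four 7-hour segments labelled A (day 2
  daytime), B (day 2 evening), C (day 3 daytime), D (day 3 evening).
* Within every stimulus hour each of the 16 sounds plays exactly once in
  random order, with consecutive onsets separated by 195–255 s so
  presentations stay unpredictable.
* The 21:00–22:00 hour of segment B is reserved for bathing and contains no
  presentations; analyses replace that hour by duplicating the following
  hour's measurements (flagged `interpolated`) so every segment keeps a
  14-hour-equivalent denominator across a two-segment treatment.
* Nights (23:30–7:30) are sleep: no usable beats.

Participants are randomized by permuted blocks (sizes 4 and 6) into two
sequence groups of a two-period crossover: Group 1 experiences segments
A+D in period 1 and B+C in period 2; Group 2 the reverse. Periods here are
treatment sequences, not calendar time.

### Crossover screening

Before pooling periods, each sound is screened for carryover and period
effects using per-participant summaries of both-period completers:

* **carryover**: the *sum* of the two periods' apparencies — a sequence
  effect shifts this sum differently between groups;
* **period effect**: *half the difference* of the two periods' apparencies.

Each summary is compared between the two sequence groups with a Welch
two-sample t-test (Satterthwaite degrees of freedom), oriented as Group 2
minus Group 1. A sound is *retained* only if both tests are non-significant
at $\alpha = 0.05$ — i.e. its noticeability is reproducible across
sequences and periods. The orientation of the period half-difference
(period 1 minus period 2 by default, switchable via
`period_orientation`) only flips the sign of $t$ and leaves $p$ unchanged,
so the screening decision is orientation-invariant; the option exists
because either convention appears in the crossover literature.

### Trial analyses

Retained sounds enter period-2 analyses on two populations:

* **ITT** (intention to treat): all participants with any period-2 data;
  missing participant × sound cells are imputed with the participant's own
  median over their observed period-2 apparencies (no information crosses
  periods).
* **PPS** (per-protocol set): completers with no imputation.

Both get a one-way ANOVA of apparency across sounds with $\eta^2 =
SS_\text{between}/SS_\text{total}$; with 18 participants and 11 sounds the
design yields the (10, 187) degrees-of-freedom shape, with 16 participants
(10, 165). Diurnal consistency is tested per sound with a paired t-test of
daytime (A, C) versus evening (B, D) apparency, reporting Cohen's
$d_z = |t|/\sqrt{n}$.

## The synthetic-data generator

`simulate_experiment()` produces everything the pipeline consumes:

```{r, eval = FALSE}
sim <- simulate_experiment(simulation_params(), scenario = "trial_profile", seed = 1)
run <- run_pipeline(data = sim, seed = 1)
```

RR intervals are generated per waking block as a baseline plus AR(1)
Gaussian noise; stimulus responses are injected by shifting the five
post-onset intervals by a fixed amount. The parameters, their defaults and
the reasoning:

| parameter | default | rationale |
|---|---|---|
| `n_participants` | 22 | the reference trial's randomized sample size |
| `block_sizes` | 4, 6 | permuted-block randomization, concealable block lengths |
| `baseline_rri_ms` | 850 ms | resting heart rate ≈ 70 bpm |
| `rri_noise_sd_ms` | 25 ms | typical short-term HRV magnitude |
| `ar1_coeff` | 0 | i.i.d. noise by default so the closed-form null rate holds exactly; set > 0 to study robustness to serial correlation |
| `diurnal_drift_ms` | 0 | optional circadian cosine (slowest ≈ 4:00) |
| `p_acc`, `p_dec` | 0.15 each | mid-range injected response probabilities |
| `response_delta_ms` | 250 ms | 10 noise SDs — an "overwhelming" response, so essentially every injected event is classified, making injected probabilities recoverable |
| `response_len_beats` | 5 | matches the post-window length |

The generator deliberately does **not** model habituation, respiration
coupling, movement artifacts, or realistic HRV spectra. Its purpose is
narrower: a ground-truth harness in which every scored label has a known
cause, so the scoring chain, the null contamination rate, and the
screening/trial statistics can be validated quantitatively.

`scenario = "trial_profile"` reproduces the reference attrition arithmetic: 22
randomized, two withdrawals per group after period 1 (ITT n = 18),
period-1 equipment failures placed so the both-period crossover set splits
8 versus 6, and scattered missing period-2 cells for two Group-2
participants (PPS n = 16).

## Numerical choices worth knowing

* Windows are located with `findInterval()` on sorted beat times; ties at
  the onset are deterministic (interval ending at the onset is *pre*, one
  starting at the onset is *post*).
* A `max_span_ms` guard (15 s per side, roughly 5 slow beats plus margin)
  prevents windows from silently bridging recording gaps such as sleep.
* RRIs outside 300–2000 ms (200–30 bpm) are flagged implausible and
  invalidate any window containing them.
* All significance machinery (`welch_t()`, `anova_oneway()`, `paired_t()`)
  wraps `stats::t.test()` / `stats::aov()` and is cross-checked in the test
  suite against independent formula-level implementations.
* Percentages are only rounded (half-up, one decimal) at the presentation
  layer; every internal computation is unrounded.
* Zero-variance and degenerate inputs (identical groups, constant paired
  differences) return explicit `degenerate` flags instead of `NaN`s.

## Limitations

The package evaluates *noticeability*, not meaning, pleasantness or
urgency. The OR threshold of 2 fixes sensitivity and false-salience rate
jointly; with only five beats per window the statistic is noisy at the
single-presentation level and becomes informative through the many repeated
presentations the protocol provides. The simulator validates software
behaviour, not human physiology: conclusions about which real sounds people
notice require real recordings.
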