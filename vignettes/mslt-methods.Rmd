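---
title: "Models and methods behind the mslt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mslt package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslt)
```

## The task

The motor sequence learning task (MSLT) probes habit formation through
overtraining of a fixed 12-item finger sequence. Four stimulus positions map
to four fingers; stimuli appear one at a time and the participant presses
the spatially corresponding key within an adaptive response window. Three
block types are interleaved in the fixed session order
random–learning–test–learning–learning–test–random, run identically on two
consecutive days:

* **random** (99 trials): pseudo-random stimuli, the RT baseline;
* **learning** (792 trials): 66 uninterrupted repetitions of the sequence;
* **test** (759 trials): the same sequence, but in every second repetition
  one item is omitted and the next item is shown directly — 33 skip events.
  Responding to a skip-successor trial with the *omitted* item's key is an
  action slip, the task's index of automatic responding.

Within learning and test blocks, 10-s break markers are placed after every
264 and 253 trials respectively; each sequenced block starts at a random
offset into the sequence so its cyclic structure is less salient. Stimulus
and feedback screen durations (400 ms / 700 ms, 100 ms inter-trial interval)
are carried in the configuration as metadata only: the simulation is
event-driven, and breaks are plan markers, not timed waits.

### Choices the design left open

The published design fixes counts and the staircase but not every generative
detail. Where a choice had to be made, it is a configuration default:

* **Sequence structure.** Each of the four positions occurs exactly three
  times and no two consecutive items are equal, including the wrap from last
  to first. Balance keeps stimulus frequency from confounding RT effects;
  the wrap constraint guarantees that the omitted item always differs from
  the item displayed in its place. (`balanced_sequence = FALSE` relaxes this
  to "all positions occur, no adjacent repeats".)
* **Pseudo-randomization of random blocks.** Shuffled balanced tiles with
  adjacent-repeat repair: per-position counts stay within one of `n/4` and
  stimuli never repeat immediately, matching the stimulus statistics of the
  sequenced blocks.
* **Skip placement.** Skips occur in the even-numbered sequence
  presentations (2nd, 4th, …), so a block always begins with an intact
  presentation — including after breaks. The skipped phases cycle through
  the twelve sequence positions without replacement (each is skipped 2 or 3
  times among the 33 events), shuffled per seed, never probing adjacent
  sequence phases in consecutive skip events and never skipping the final
  trial of a block (which would have no successor to probe).
* **Practice.** A short warm-up block (36 pseudo-random trials by default)
  runs under a generous deadline solely to estimate the practice median RT
  that seeds the staircase; its trials are not part of the scored log.
* **Skip schedules and start offsets** are seed-controlled per session plan
  and, by default, shared by all simulated participants of a study, mirroring
  a fixed experimental protocol.

## The adaptive deadline

Each block begins with a response limit of twice the practice-block median
RT. After every completed run of three consecutive correct responses the
limit drops by 30 ms; after an error it is set to 1.5 times the median of
the correct RTs observed so far in the current block (the practice median
stands in while that set is empty). Medians use linear interpolation for
even counts. Three readings were fixed here:

* **"Incorrect" includes too-slow trials.** Both wrong-key and too-slow
  outcomes reset the correct-response streak and trigger the ×1.5
  relaxation; both are failures of the speed/accuracy demand
  (`penalize_too_slow = FALSE` restricts the relaxation to wrong keys).
* **"Median RT of the current block"** is computed over correct responses
  only — too-slow trials have no RT to contribute.
* **A floor of 150 ms** (configurable) clamps the limit so the staircase
  cannot outrun any plausible responder; the counter resets to zero after
  each 30-ms step, so a decrement needs a fresh run of three.

Within-block breaks do not touch the staircase; block boundaries reset it.

## The synthetic participant

No computational participant model accompanies the task; the agent here is
declared synthetic, chosen for monotonicity and closed-form testability
rather than cognitive fidelity. Expected RT on trial $n$ is

$$\mu = \text{base} - g\,(1 - e^{-n/\tau}) - s\,H\,[\text{sequenced}]$$

truncated at a 50-ms physiological floor, with additive Gaussian noise
(also truncated at the floor). Sequence knowledge is a scalar association
strength $H \in [0,1]$ updated as $H \leftarrow H + \text{rate}\,(1-H)$ on
every sequenced trial — so $H = 1-(1-\text{rate})^k$ after $k$ sequenced
trials — and untouched by random trials. On a skip-successor trial the agent
anticipates the omitted item with probability

$$p_{\text{slip}} = \text{slip\_gain} \cdot H \cdot
  \sigma\!\left(\frac{\mu - \text{deadline}}{\text{scale}}\right),$$

multiplicative so that slips require both learned associations ($H > 0$) and
a mechanism ($\text{slip\_gain} > 0$), and increase monotonically with
deadline pressure. Otherwise the agent responds to the displayed stimulus,
with a wrong-key lapse probability. A drawn RT above the deadline is a
non-response (too slow); a non-response on a skip trial is *not* a slip —
slips are erroneous key presses. Agent state persists across the two
sessions (scaled by a consolidation factor, default 1), so day 2 starts from
trained behavior.

### Cohort defaults

Cohort heterogeneity comes from truncated-normal hyper-distributions over
the agent parameters (`mslt_config()$agents$hyper`), with a default cohort
size of 31. The defaults were set once to produce a cohort that behaves like
trained human participants at this task's scale: baseline RTs near 430 ms
narrowing to low-200s medians after two days; a general practice gain of
~90 ms with a time constant of ~2000 trials; a sequence-specific gain of
~160 ms; association rates averaging 1.8×10⁻⁴ per sequenced trial, so $H$
is still rising at the end of session 2 (≈0.13 → ≈0.72 across the four test
blocks) rather than saturating on day 1; and a wide spread of association
rates, which makes automaticity the dominant source of individual
differences. That spread is what couples speed to slips between subjects:
fast learners are both faster (larger $s\,H$) and more slip-prone (larger
$H$), producing the negative test-block correlations between median RT and
slip count, and it gives slip counts enough stable between-subject variance
for a positive test–retest reliability. The logistic pressure scale
(~250 ms) sets how strongly the staircase's pressure converts association
strength into anticipations.

### What the generator does not emulate

Passing tests on this cohort show that the pipeline recovers the *direction*
of the task's phenomena from trial-level logs — not that the model captures
human behavior. In particular: slip probabilities are capped near one half
of `slip_gain · H` because the staircase keeps the deadline at or above the
block median RT, so absolute slip counts run lower than trained humans
show; there is no explicit sequence awareness, no fatigue or
time-of-day effects, no per-transition (chunked) learning — association is a
single scalar (a per-transition table is a documented extension point); and
between-session consolidation is a bare multiplicative carry-over. Cohort
statistics (F values, correlations, reliable-change rates) are therefore
comparable to human data in sign and ordering, not magnitude.

## Scoring and statistics

Scoring is a pure function of the event log. Per (participant, session,
block) cell: the median RT over correct responses only; the error rate as
wrong-key responses divided by trials in the block (too-slow responses are
a separate rate by default — `errors_include_too_slow` folds them in); and
the action-slip count. A cell with no correct trials yields a missing median
and a degeneracy flag rather than a silent zero. The first/last analysis
cells map to blocks 1/7 (random), 2/5 (learning — the third learning block
is "last"), and 3/6 (test).

The repeated-measures ANOVA uses the univariate decomposition with subject
as the random factor: each within-subject effect is projected onto an
orthonormal contrast basis (polynomial contrasts per factor, Kronecker
products for interactions), its error term is its interaction with subjects,
and Greenhouse–Geisser epsilon is estimated from the covariance of the
contrast scores, clamped to $[1/df, 1]$. With the task's all-two-level
design every effect has one degree of freedom and the correction is vacuous
(ε = 1 exactly); the machinery is implemented generally so unbalanced-level
factors (e.g. four test blocks as one factor) can reuse it. Effect sizes are
partial eta squared, $SS_e/(SS_e + SS_{err})$. Designs with missing cells
are rejected — no imputation. Post-hoc paired t-tests are Bonferroni
adjusted ($p_{adj} = \min(1, m\,p)$); zero-variance differences are flagged
(t = 0, p = 1 for identical vectors; infinite t for constant nonzero
differences) rather than erroring.

The reliable change index is
$\text{RCI} = (X_2 - X_1)/S_{\text{diff}}$ with
$S_{\text{diff}} = \sqrt{2\,SE^2}$ and $SE = SD\sqrt{1 - r_{xx}}$, where
$X_1$/$X_2$ are a participant's slip counts in the first test block of
session 1 and the last test block of session 2 and $SD$ is the cohort SD of
$X_1$; values at or above 1.96 mark a reliable increase. The reliability
$r_{xx}$ is not published for this measure, so the default estimator is the
Pearson correlation between the two test blocks of session 1 (internal
test–retest); it is a free argument, and a negative estimate — possible in
small or barely-trained cohorts where binomial noise dominates — is clamped
to zero with a warning, which reduces $SE$ to the full cohort SD, the most
conservative criterion. Degenerate inputs ($SD = 0$ or $r_{xx} = 1$) raise
errors, since the index is undefined there.

## Numerical and interface choices

RTs are recorded at 0.1-ms and deadlines at 0.001-ms resolution; every
staircase update re-rounds the limit to that grid. Because all logged
numerics are short decimal strings, the CSV round trip
(`read_log(write_log(x))`) is field-exact, and re-writing a read log
reproduces the file byte for byte. All generators are pure functions of
(configuration, seed): seeds are consumed through an internal scope that
restores the caller's RNG state, and study-level seeds derive per-plan and
per-participant child seeds. Every numeric design constant lives once, in
`mslt_config()`.

## Problem sizes used in the test suite

Unit tests run on miniature configurations (6 sequence repetitions,
24-trial random blocks) where a session takes milliseconds; structural
assertions and one full-size session use the published dimensions. The
cohort-level checks simulate 20 independent 31-participant studies at full
size and assert the direction of the three headline phenomena on them:
session-2 learning blocks faster than random blocks; grand-mean slips
strictly increasing over the four test blocks; and a negative final-test-
block correlation between median RT and slips in at least 19 of the 20
replicates (the per-replicate criterion uses the final test block, where
training is maximal and the correlation least noisy; per-block means are
additionally required to be negative). ANOVA calibration uses 2000 null
replicates of a 2×2×2 design with 31 subjects, requiring each effect's
rejection rate at α = .05 to lie in [0.04, 0.06].

## Known limitations

* The agent's slip ceiling (see above) compresses the dynamic range of slip
  counts relative to overtrained humans.
* `estimate_rxx` treats the two session-1 test blocks as parallel forms,
  but training continues between them; the estimate is conservative.
* The ANOVA requires complete balanced within-subject data; participants
  with missing cells must be excluded upstream.
* The CLI import path expects this package's CSV schema; adapters for other
  experiment software's native logs are an extension point, not included.
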