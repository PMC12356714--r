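# mslt: simulation and analysis of a motor sequence learning task with skip probes

`mslt` is an R toolkit for a serial-response **motor sequence learning task
(MSLT)** used to study habit formation. Participants respond with four
fingers to visual stimuli at four screen positions. Training blocks repeat a
fixed 12-item sequence; interleaved **test blocks** omit single sequence
items ("skip events"), and responding with the key of the *omitted* item
instead of the displayed one — an **action slip** — indexes automatic,
habitual responding. The task is paced by an **adaptive response deadline**:
each block starts at twice the practice-block median RT, the limit tightens
by 30 ms after every three consecutive correct responses and relaxes to 1.5
times the current-block median RT after an error, keeping participants under
constant time pressure.

The package provides, end to end:

* **Task generation** — trial-exact plans: pseudo-random baseline blocks (99
  trials), learning blocks (792 trials = 66 repetitions of the sequence),
  test blocks (759 trials containing exactly 33 skip events), in the session
  order random–learning–test–learning–learning–test–random, with break
  markers and randomized sequence start offsets.
* **Pacing** — the deadline staircase as a small, replayable state machine.
* **Synthetic participants** — a generative agent with practice-dependent
  RT speed-up, sequence-specific gains driven by an association strength
  `H ∈ [0,1]` (`H ← H + rate·(1−H)` on sequenced trials), wrong-key lapses,
  and anticipatory slips with probability
  `p_slip = slip_gain · H · σ((μ − deadline)/scale)`.
* **Engine** — runs agents through session plans, emitting tidy trial-level
  event logs (CSV round trip is field-exact).
* **Metrics** — correct-only median RTs, error rates, slip counts, the
  reliable change index `RCI = (X₂ − X₁)/S_diff` with
  `S_diff = √(2·SE²)`, `SE = SD·√(1 − r_xx)` (cutoff 1.96), and
  speed–accuracy correlations.
* **Within-subject statistics** — repeated-measures ANOVA with
  Greenhouse–Geisser correction and partial eta squared, paired t-tests,
  Bonferroni adjustment.

## Worked example

```r
library(mslt)

cfg   <- mslt_config()                 # the published task design
study <- run_study(n_participants = 31, config = cfg, seed = 42)
cells <- summarize_cells(do.call(rbind, lapply(study$logs, as.data.frame)))
slip_table(cells)[1:3, 1:5]
#>   participant_id s1_first s1_last s2_first s2_last
#> 1              1        0       8        7      14
#> 2              2        6       9        9       8
#> 3              3        6       6        7      13

report <- analyze_summaries(cells)
report$slip_anova
#> Repeated-measures ANOVA (Greenhouse-Geisser corrected)
#>         effect      F      df     p_gg epsilon peta2
#>        session 80.894 (1, 30) 5.09e-10   1.000 0.729
#>          block 18.926 (1, 30) 0.000145   1.000 0.387
#>  session:block  9.829 (1, 30) 0.003825   1.000 0.247
```

Slip counts rise from the first test block of session 1 to the last test
block of session 2 (habit formation with extensive training); the session ×
block ANOVA quantifies that growth. `report$rci` gives each participant's
reliable-change index for the slip increase, `report$correlations` the
per-test-block Pearson correlations between median RT and slip count
(negative: faster responders slip more), and `report$rt_anova` the
session × block × condition ANOVA on correct-only median RTs showing
sequence learning (learning blocks faster than random blocks).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/mslt.R fixtures --preset paper-default --out cfg.yaml
Rscript inst/cli/mslt.R simulate --config cfg.yaml --n 31 --seed 42 --out logs/
Rscript inst/cli/mslt.R score    --logs logs/ --out summaries.csv
Rscript inst/cli/mslt.R analyze  --summaries summaries.csv --out report.json
```

Event logs written by external experiment software can enter the pipeline at
the `score` step, provided they use the documented CSV schema (one row per
trial: `participant_id, session_id, block_index, condition, trial_index,
stimulus, seq_phase, is_skip_successor, omitted_stimulus, response, rt_ms,
deadline_ms, outcome, action_slip`).

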