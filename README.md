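# seqtime

Analysis of dorsal-CA1 two-photon calcium imaging recorded during a
**differential delayed-non-match-to-sample (dDNMS)** task — a working-memory
task with an implicit-timing structure: odor A or B is presented for 1 s,
the *identity* of that first odor cues the delay duration (2.5 s after the
short cue, 5.0 s after the long cue), a second odor follows, and licks
during a 3-s response window are rewarded on non-match trials. On 20% of
trials the cue-delay contingency is reversed, probing whether the animal
(and its hippocampal activity) learned the task-irrelevant temporal
structure.

The package is aimed at systems neuroscientists analyzing deconvolved
population recordings from this task family. It covers, end to end:

* **Behavior** — accuracy and first-lick latency per trial category
  (standard/reverse x short/long), paired session-level comparisons, and
  locomotion scoring (z-binned traces, >= 1 s running bouts, per-trial
  running flags).
* **Conditioning & alignment** — rolling mean (10 frames), session
  z-score with a 2-STD floor ("firing rate (STD)"), and trial alignment
  into 5-frame (0.16 s) bins over a [-2, 11] s window.
* **Sequence-cell detection** — per neuron: preferred trial type (larger
  average peak), then significance iff the trial-averaged peak exceeds the
  95th percentile of 2000 circular shuffles *and* >= 20% of preferred
  trials show a >= 2 STD event within 0.5 s of the peak. In symbols, with
  shuffle maxima `m_1..m_2000` of the rotated trial-average:
  `significant(i) <=> peak_i > Q95({m_s}) AND rel_i >= 0.2`.
* **Trajectory geometry** — distance from the pre-odor baseline state and
  speed between neighboring bins, both Euclidean in full dimensional space
  and divided by `sqrt(n)` significant cells; per-bin condition tests with
  animal/day factors and Benjamini-Hochberg adjustment (p < 0.01).
* **Odor information & time decoding** — per-neuron mutual information
  (bits/cell) between a -1.5 s baseline bin and every other bin with
  activity discretized into 20 levels; multiclass decoding of elapsed time
  (1.1-3.4 s, 7 classes of 1/3 s) with a one-vs-one linear max-margin
  decoder under trial-grouped 5-fold cross-validation, scored as the
  correlation of actual and predicted bins.
* **Synthetic sessions** — a generator that emulates the task schedule,
  odor-specific sequence cells tiling the delays (with a configurable
  over-representation of the last 0.5 s of the short delay), behavior and
  locomotion, returning planted ground truth so every stage has
  parameter-recovery tests.

## Worked example

```r
library(seqtime)

cfg <- task_config(iti = 2)          # default task, short ITI for speed
ses <- generate_session(cfg,
         generator_params(n_sequence_cells = 20, n_second_odor_cells = 4,
                          n_noise_cells = 60, overrep_weight = 0.3),
         seed = 1)

rec <- ses$recording
rec$activity <- condition_signal(rec$activity)  # smooth, z-score, floor
al  <- align(rec)                                # 108 x 140 x 80 tensor
tr  <- rec$trials

summarize_behavior(tr, cfg)
#>         category n_trials accuracy_pct median_latency_ms
#> 1 standard_short       56     83.92857          560.8149
#> 2  standard_long       56     85.71429          543.4539
#> 3  reverse_short       14     92.85714          453.0670
#> 4   reverse_long       14     85.71429          610.5890
#> 5       standard      112     84.82143          548.1354
#> 6        reverse       28     89.28571          573.3691

st <- detect_sequence_cells(al, tr, cfg, detection_params(), seed = 2)
sum(st$significant)                  # 41 of 108 neurons
table(st$preferred[st$significant])  # short: 21, long: 20
```

The 41 significant cells are (mostly) the 40 planted sequence cells; their
`peak_time` recovers the planted field centers to within one 0.16-s bin.
Downstream, the planted anticipatory cluster at the end of the short delay
shows up exactly where the method looks for it:

```r
ss <- tr$index[!tr$is_reverse & tr$odor1 == "A"]  # standard short trials
sl <- tr$index[!tr$is_reverse & tr$odor1 == "B"]  # standard long trials
sc <- st$neuron[st$significant & st$preferred == "short"]
lc <- st$neuron[st$significant & st$preferred == "long"]

vs <- trajectory_speed(condition_mean(al, ss, sc))  # a.u., sqrt(n)-normalized
vl <- trajectory_speed(condition_mean(al, sl, lc))
# mean speed in the last second of the short delay:
#   standard short 1.07 vs standard long 0.877

decode_time(al, ss, seed = 3)$score  # 0.963  (standard short)
decode_time(al, sl, seed = 3)$score  # 0.938  (standard long)
```

Time decoding is near-perfect on both conditions at this planted SNR and
higher for the cued-short trials, whose tiling was planted denser near the
expected second odor; with permuted labels the same decoder scores ~0
(chance) — that calibration is what the acceptance report measures.

## Command line

A thin CLI wraps the main stages:

```sh
seqtime synth --seed 1 --out session.dir --truth truth.csv
seqtime validate session.dir
seqtime detect session.dir --out cells.csv --seed 2
seqtime behavior session.dir --out behavior.csv
```

Sessions are directories of plain-text files (`meta.json`, `activity.tsv`,
`trials.csv`, `locomotion.tsv`) with exact double round-tripping.

See `vignettes/seqtime-methods.Rmd` for the model, every tunable parameter
with its default and rationale, what the synthetic generator does and does
not emulate, and known limitations.
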