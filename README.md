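# pursuitlab

Simulation and analysis of hidden-intention inference in a prey-pursuit
game.

Three agents move in a 1920 x 1080 arena at 60 Hz: a fleeing prey, a
player, and a computer opponent whose hidden intention is a scalar
`F ∈ [0, 1]` — `F = 0` intercepts the prey for itself, `F = 1` herds it
toward the player. Observers watch an inference phase, choose to boost or
hinder the opponent for the upcoming pursuit, and are rewarded by capture
speed; between the two phases the experimenter covertly changes `F` by
`ΔF` (negative = betrayal, positive = unexpected help). The scientific
questions are how people infer `F` from motion, how betrayal history
biases that inference, and how the bias can be described as a shifted
attractor in an energy landscape over the inferred intention.

`pursuitlab` is for researchers who want this entire paradigm as
reusable, tested code without human data:

- **Game engine** (Rcpp core): prey escape/centrality policy over 15
  candidate headings 24° apart, opponent policy minimizing
  `F·d_play + (1−F)·d_oppo` from a one-step prey prediction, autopilot
  player with a 750 ms prediction horizon, phase runners, conditioning
  schedules, and the 100-to-0-point linear reward rule with the
  opponent-capture share `score × F × 0.5`.
- **Synthetic participants**: boost/hinder choices from
  `logit P(boost) = β0 + βt·X + β_hys·ΔF_prev` with known ground truth,
  gaze that shifts toward the opponent ~1.1 s into betrayal pursuits, and
  joystick jitter that grows with gaze distance from the own avatar.
- **Analyses**: cumulative-Gaussian psychometrics and JND, inferential
  bias, binary choice entropy, signal detection (`d′`, criterion `c`),
  the autoregressive logistic inference model, frame-by-frame inferred-F
  series, binned drift `g(F̂)`, potentials `U(F̂) = −∫g` (signed mode) or
  `∫|g|` (printed form), AIC-selected polynomial fixed points with basin
  depth/steepness, ternary gaze weights, jerk strength, partial Spearman
  correlations, and a cluster-based permutation test for paired time
  series.
- **A three-step LSTM experiment** (hand-rolled batched BPTT, no deep
  learning dependency): F-prediction training, betrayal/help adaptation
  under the asymmetric loss `β_bet·L⁻ + (1−β_bet)·L⁺` with bifurcation to
  the 0.9/0.1 extremes, per-channel input-weight change norms, and the
  input-weight sign-reversal intervention.

## Worked example

```r
library(pursuitlab)
library(dplyr)

ds <- generate_dataset(n_participants = 4, n_trials = 150,
                       experiment = 1, seed = 420, pursuit = FALSE)

# psychometric curve of the boost choice over the given F
glance(fit_psychometric(ds$trials))
#> # A tibble: 1 × 6
#>      mu sigma   jnd    sse     n degenerate
#>   <dbl> <dbl> <dbl>  <dbl> <int> <lgl>
#> 1 0.668 0.650 0.438 0.0808   600 FALSE

# competitive bias after betrayal, none after unexpected help
ds$trials |>
  group_by(participant) |>
  mutate(prev = lag(condition)) |>
  ungroup() |>
  filter(!is.na(prev)) |>
  group_by(prev) |>
  summarise(bias = mean(choice_bin - f_inference))
#> # A tibble: 2 × 2
#>   prev                bias
#>   <chr>              <dbl>
#> 1 betrayal        -0.170
#> 2 unexpected_help -0.00629
```

`mu` is the point of subjective equality (the given F at which boost and
hinder are equally likely), `sigma` the psychometric spread, and the JND
is `0.6745·sigma`. The bias table shows the headline hysteresis pattern:
choices after betrayal rate the opponent's intention below its actual
value (negative bias), while choices after unexpected help do not — here
with the generator's default hysteresis weight `β_hys = 2`.

Per-participant inference models and condition landscapes:

```r
models <- ds$trials |>
  group_by(participant) |>
  group_map(~ fit_autoregressive_logit(.x))
sapply(models, function(m) m$beta_hys)
#> [1] 2.39 1.17 3.42 3.42     # ground truth ~ 2
```

## Package layout

- `R/engine.R`, `src/engine.cpp` — game policies and phase runners
- `R/schedule.R` — betrayal/help conditioning schedules (blocked, zigzag)
- `R/participant.R` — synthetic-participant generator
- `R/behavior.R` — psychometrics, entropy, SDT, reward sensitivity
- `R/landscape.R` — inference model, drift, potentials, basin geometry
- `R/gaze.R` — gaze allocation, jerk, partial correlations, permutation
  test
- `R/rnn.R` — the LSTM experiment
- `R/io.R` — trial-log/trajectory CSV formats, manifests, the pipeline
  driver
- `vignettes/pursuit-inference-landscapes.Rmd` — the methods vignette
  (models, assumptions, design decisions, limitations)
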