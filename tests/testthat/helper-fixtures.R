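# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

# A small Experiment-1 cohort with hysteresis, inference phases only.
small_dataset <- function() {
  if (is.null(fixture_cache$small)) {
    fixture_cache$small <- generate_dataset(
      n_participants = 4, n_trials = 150, experiment = 1,
      seed = 420, pursuit = FALSE)
  }
  fixture_cache$small
}

small_models <- function() {
  if (is.null(fixture_cache$small_models)) {
    ds <- small_dataset()
    fixture_cache$small_models <- ds$trials |>
      dplyr::group_by(participant) |>
      dplyr::group_map(~ fit_autoregressive_logit(.x))
  }
  fixture_cache$small_models
}

# Trials with the previous trial's condition attached.
with_prev_condition <- function(trials) {
  trials |>
    dplyr::group_by(participant) |>
    dplyr::mutate(prev_condition = ifelse(trial == 1, NA,
                                          dplyr::lag(condition))) |>
    dplyr::ungroup()
}
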