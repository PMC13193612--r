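#' Build a conditioning schedule
#'
#' Experiment 1 alternates betrayal and unexpected-help blocks of 20 +/- 4
#' trials; within a block the signed change in intention `delta_f` is drawn
#' uniformly from the 0.35 to 0.45 magnitude band (negative in betrayal
#' blocks). Experiment 2 sweeps `delta_f` in a zigzag: from -0.45 to +0.45
#' in nine equal steps, then back, alternating direction. In both cases the
#' inference-phase F is uniform on `[0, 1]` and the pursuit-phase F is
#' `f_inference + delta_f` clamped to `[0, 1]`.
#'
#' @param experiment 1 or 2.
#' @param n_trials number of trials.
#' @param cfg a [game_config()] (kept for interface symmetry).
#' @return A tibble with one row per trial: `trial`, `block` (Exp 1) or
#'   `leg` (Exp 2), `phase` (Exp 2: `delta_f` trend, `"increasing"` or
#'   `"decreasing"`), `condition` (`"betrayal"` iff `delta_f < 0`, else
#'   `"unexpected_help"`; `"neutral"` at `delta_f == 0`), `f_inference`,
#'   `delta_f`, `f_pursuit`.
#' @export
#' @examples
#' set.seed(1)
#' make_schedule(1, 40)
make_schedule <- function(experiment = c(1, 2), n_trials,
                          cfg = game_config()) {
  experiment <- match.arg(as.character(experiment), c("1", "2"))
  stopifnot(n_trials > 0)
  if (experiment == "1") {
    sched <- schedule_exp1(n_trials)
  } else {
    sched <- schedule_exp2(n_trials)
  }
  sched$f_inference <- runif(n_trials)
  sched$f_pursuit <- pmin(pmax(sched$f_inference + sched$delta_f, 0), 1)
  sched$condition <- dplyr::case_when(
    sched$delta_f < 0 ~ "betrayal",
    sched$delta_f > 0 ~ "unexpected_help",
    .default = "neutral"
  )
  cols <- intersect(c("trial", "block", "leg", "phase", "condition",
                      "f_inference", "delta_f", "f_pursuit"), names(sched))
  dplyr::select(sched, dplyr::all_of(cols))
}

schedule_exp1 <- function(n_trials) {
  block <- integer(0)
  sign_of <- numeric(0)
  b <- 1L
  s <- sample(c(-1, 1), 1)  # first block condition random
  while (length(block) < n_trials) {
    len <- 20L + sample(-4:4, 1)
    block <- c(block, rep(b, len))
    sign_of <- c(sign_of, rep(s, len))
    b <- b + 1L
    s <- -s
  }
  block <- block[seq_len(n_trials)]
  sign_of <- sign_of[seq_len(n_trials)]
  tibble::tibble(
    trial = seq_len(n_trials),
    block = block,
    delta_f = sign_of * runif(n_trials, 0.35, 0.45)
  )
}

schedule_exp2 <- function(n_trials) {
  step <- 0.9 / 8  # nine values from -0.45 to 0.45
  vals <- numeric(n_trials)
  leg <- integer(n_trials)
  phase <- character(n_trials)
  v <- -0.45
  dir <- +1
  l <- 1L
  for (i in seq_len(n_trials)) {
    vals[i] <- v
    leg[i] <- l
    phase[i] <- if (dir > 0) "increasing" else "decreasing"
    nxt <- v + dir * step
    if (nxt > 0.45 + 1e-9 || nxt < -0.45 - 1e-9) {
      dir <- -dir
      l <- l + 1L
      nxt <- v + dir * step
    }
    v <- nxt
  }
  tibble::tibble(trial = seq_len(n_trials), leg = leg, phase = phase,
                 delta_f = vals)
}

#' Label given-F terciles
#'
#' Adds the low / medium / high grouping of the inference-phase F used when
#' landscapes are compared across conditions (low: F < 1/3, medium,
#' high: F > 2/3).
#'
#' @param data a data frame with the F column.
#' @param f column holding the inference-phase F (tidy-eval).
#' @return `data` with an added `f_tercile` factor.
#' @export
label_terciles <- function(data, f = f_inference) {
  data |>
    dplyr::mutate(
      f_tercile = cut({{ f }}, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                      labels = c("low", "medium", "high"))
    )
}
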