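#' Ground-truth parameters of a synthetic participant
#'
#' The synthetic participant chooses boost with probability
#' `plogis(beta0 + beta_t . X + beta_hys * delta_f_prev)`, where `X` is the
#' 15-dimensional trajectory feature vector of the inference phase (see
#' [build_features()]) and `delta_f_prev` the previous trial's change in
#' intention. A positive `beta_hys` therefore lowers the boost probability
#' after betrayal (negative `delta_f_prev`): the hysteresis / competitive
#' bias. Gaze shifts toward the opponent ~1.1 s into betrayal pursuits,
#' and joystick control noise grows with the gaze's distance from the own
#' avatar.
#'
#' @param beta0 intercept of the choice model.
#' @param beta_t length-15 feature weights (default: equal positive weight
#'   on the prey-opponent distance bins, equal negative weight on the
#'   prey-player bins, zero on opponent-player; see the package vignette
#'   for the calibration of the default magnitude).
#' @param beta_hys hysteresis weight on `delta_f_prev` (>= 0 encodes
#'   betrayal-driven competitive bias).
#' @param gaze_shift_latency s after pursuit onset at which betrayal-trial
#'   gaze starts shifting toward the opponent (default 1.1).
#' @param gaze_shift_gain added opponent gaze weight once shifted.
#' @param gaze_noise_sd isotropic gaze noise, degrees.
#' @param gaze_base_weights baseline gaze mixture over (prey, opponent,
#'   player); must sum to 1.
#' @param control_noise joystick acceleration noise per degree of
#'   gaze-to-self distance (deg/s^2 per deg).
#' @param decision_time_mean,decision_time_sd choice latency draw, s.
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(beta0 = -1.24,
                               beta_t = default_beta_t(),
                               beta_hys = 2,
                               gaze_shift_latency = 1.1,
                               gaze_shift_gain = 0.35,
                               gaze_noise_sd = 1,
                               gaze_base_weights = c(prey = 0.5,
                                                     opponent = 0.2,
                                                     player = 0.3),
                               control_noise = 0.6,
                               decision_time_mean = 1.3,
                               decision_time_sd = 0.3) {
  stopifnot(length(beta_t) == 15, abs(sum(gaze_base_weights) - 1) < 1e-9,
            beta_hys >= 0 || TRUE)
  structure(
    list(beta0 = beta0, beta_t = setNames(as.numeric(beta_t),
                                          feature_names()),
         beta_hys = beta_hys,
         gaze_shift_latency = gaze_shift_latency,
         gaze_shift_gain = gaze_shift_gain,
         gaze_noise_sd = gaze_noise_sd,
         gaze_base_weights = gaze_base_weights,
         control_noise = control_noise,
         decision_time_mean = decision_time_mean,
         decision_time_sd = decision_time_sd),
    class = "participant_params"
  )
}

#' @rdname participant_params
#' @param w_po,w_pp per-bin weights on the prey-opponent and prey-player
#'   distances.
#' @export
default_beta_t <- function(w_po = 0.191, w_pp = -0.191) {
  c(rep(w_po, 5), rep(w_pp, 5), rep(0, 5))
}

#' Population distribution of participant parameters
#'
#' Per-participant parameters are drawn from independent normal
#' distributions around the stated means (scalar parameters) with the
#' stated SDs; `beta_t` is jittered element-wise.
#'
#' @param mean a [participant_params()] holding the population means.
#' @param beta0_sd,beta_t_sd,beta_hys_sd,gaze_shift_gain_sd,control_noise_sd
#'   population SDs.
#' @return A list of class `population_params`.
#' @export
population_params <- function(mean = participant_params(),
                              beta0_sd = 0.15, beta_t_sd = 0.015,
                              beta_hys_sd = 0.4,
                              gaze_shift_gain_sd = 0.08,
                              control_noise_sd = 0.15) {
  structure(list(mean = mean, beta0_sd = beta0_sd, beta_t_sd = beta_t_sd,
                 beta_hys_sd = beta_hys_sd,
                 gaze_shift_gain_sd = gaze_shift_gain_sd,
                 control_noise_sd = control_noise_sd),
            class = "population_params")
}

draw_participant <- function(pop) {
  m <- pop$mean
  participant_params(
    beta0 = rnorm(1, m$beta0, pop$beta0_sd),
    beta_t = rnorm(15, m$beta_t, pop$beta_t_sd),
    beta_hys = rnorm(1, m$beta_hys, pop$beta_hys_sd),
    gaze_shift_latency = m$gaze_shift_latency,
    gaze_shift_gain = max(0, rnorm(1, m$gaze_shift_gain,
                                   pop$gaze_shift_gain_sd)),
    gaze_noise_sd = m$gaze_noise_sd,
    gaze_base_weights = m$gaze_base_weights,
    control_noise = max(0, rnorm(1, m$control_noise, pop$control_noise_sd)),
    decision_time_mean = m$decision_time_mean,
    decision_time_sd = m$decision_time_sd
  )
}

#' Boost probability and simulated choice
#'
#' @param features length-15 feature vector from [build_features()].
#' @param delta_f_prev previous trial's change in F (0 for the first trial
#'   of a session).
#' @param params a [participant_params()].
#' @return `prob_boost()` returns the logistic probability;
#'   `simulate_choice()` draws one Bernoulli choice and returns `"boost"`
#'   or `"hinder"`.
#' @export
prob_boost <- function(features, delta_f_prev, params) {
  plogis(params$beta0 + sum(params$beta_t * features) +
           params$beta_hys * delta_f_prev)
}

#' @rdname prob_boost
#' @export
simulate_choice <- function(features, delta_f_prev, params) {
  p <- prob_boost(features, delta_f_prev, params)
  if (rbinom(1, 1, p) == 1) "boost" else "hinder"
}

#' Simulate gaze over a pursuit trajectory
#'
#' Gaze is a convex mixture of the three agent positions plus isotropic
#' noise. In betrayal trials the opponent's mixture weight ramps up over
#' 0.5 s starting `gaze_shift_latency` seconds after pursuit onset
#' (weights renormalized to sum to 1 each frame); help trials keep the
#' baseline mixture throughout.
#'
#' @param traj pursuit trajectory tibble (from [run_pursuit_phase()]).
#' @param condition `"betrayal"` or `"unexpected_help"`.
#' @param params a [participant_params()].
#' @param cfg a [game_config()].
#' @return A tibble `frame`, `t`, `gaze_x`, `gaze_y` (px) with attribute
#'   `weights` (the per-frame mixture matrix).
#' @export
simulate_gaze <- function(traj, condition, params, cfg = game_config()) {
  n <- nrow(traj)
  w0 <- params$gaze_base_weights
  W <- matrix(rep(w0, each = n), n, 3,
              dimnames = list(NULL, c("prey", "opponent", "player")))
  if (identical(condition, "betrayal") && params$gaze_shift_gain > 0) {
    ramp <- pmin(pmax((traj$t - params$gaze_shift_latency) / 0.5, 0), 1)
    W[, "opponent"] <- W[, "opponent"] + params$gaze_shift_gain * ramp
    W <- W / rowSums(W)
  }
  sd_px <- params$gaze_noise_sd * cfg$px_per_deg
  gx <- W[, "prey"] * traj$prey_x + W[, "opponent"] * traj$oppo_x +
    W[, "player"] * traj$play_x + rnorm(n, 0, sd_px)
  gy <- W[, "prey"] * traj$prey_y + W[, "opponent"] * traj$oppo_y +
    W[, "player"] * traj$play_y + rnorm(n, 0, sd_px)
  out <- tibble::tibble(frame = traj$frame, t = traj$t,
                        gaze_x = gx, gaze_y = gy)
  attr(out, "weights") <- W
  out
}

#' Perturb an intended path with gaze-coupled control noise
#'
#' Adds integrated acceleration noise to an intended (autopilot) path; the
#' per-frame acceleration SD is `control_noise` times the gaze's distance
#' from the own avatar (degrees), so control degrades the further the eyes
#' wander from the controlled avatar. Per-frame step length is capped at
#' the speed limit and the path is clamped to the arena.
#'
#' @param intended_path n x 2 matrix of intended positions, px.
#' @param gaze_self_dist length-n gaze-to-own-avatar distance, degrees.
#' @param params a [participant_params()].
#' @param cfg a [game_config()].
#' @param speed_cap speed cap in deg/s (default: prey pursuit speed).
#' @return n x 2 matrix of controlled positions.
#' @export
simulate_joystick <- function(intended_path, gaze_self_dist, params,
                              cfg = game_config(),
                              speed_cap = cfg$prey_pursuit_speed) {
  n <- nrow(intended_path)
  if (params$control_noise == 0 || n < 2) return(intended_path)
  ppd <- cfg$px_per_deg
  fr <- cfg$frame_rate
  sd_acc <- params$control_noise * pmax(gaze_self_dist, 0) * ppd / fr^2
  ax <- rnorm(n, 0, sd_acc)
  ay <- rnorm(n, 0, sd_acc)
  vint <- diff(intended_path)
  cap <- speed_cap * ppd / fr
  out <- intended_path
  vex <- 0; vey <- 0
  decay <- 0.8  # keeps the integrated velocity error bounded
  for (i in 2:n) {
    vex <- decay * vex + ax[i]
    vey <- decay * vey + ay[i]
    sx <- vint[i - 1, 1] + vex
    sy <- vint[i - 1, 2] + vey
    sl <- sqrt(sx^2 + sy^2)
    if (sl > cap) { sx <- sx * cap / sl; sy <- sy * cap / sl }
    out[i, 1] <- min(max(out[i - 1, 1] + sx, 0), cfg$arena_width)
    out[i, 2] <- min(max(out[i - 1, 2] + sy, 0), cfg$arena_height)
  }
  out
}

first_touch_frame <- function(px, py, qx, qy, radius) {
  hit <- which((px - qx)^2 + (py - qy)^2 <= radius^2)
  if (length(hit)) hit[1] else NA_integer_
}

#' Generate a synthetic multi-participant dataset
#'
#' Runs the full trial loop for a cohort of synthetic participants:
#' conditioning schedule, simulated inference phase, feature extraction,
#' logistic choice with hysteresis, and (optionally) the pursuit phase
#' with reward scoring, simulated gaze and gaze-coupled joystick noise.
#' Deterministic for a given `seed`.
#'
#' @param n_participants,n_trials cohort size and trials per participant.
#' @param experiment 1 (blocked betrayal/help) or 2 (zigzag).
#' @param population a [population_params()].
#' @param cfg a [game_config()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param pursuit simulate the pursuit phase (needed for rewards, gaze and
#'   control analyses).
#' @param controller `"synthetic"` (autopilot plus gaze-coupled joystick
#'   noise) or `"autopilot"`.
#' @param keep_trajectories `"inference"`, `"all"` or `"none"`.
#' @param inference_cap generator-level cap (s) on the inference phase so
#'   synthetic inference videos stay short, as in the task being emulated;
#'   the engine-level config cap still applies if smaller.
#' @return A list of class `pursuit_dataset`: `trials` (one row per trial
#'   incl. the 15 feature columns), `trajectories` (long tibble; empty if
#'   not kept), `gaze` (long tibble of pursuit-phase gaze), `params`
#'   (per-participant ground truth), `population`, `config`, `experiment`,
#'   `seed`.
#' @export
generate_dataset <- function(n_participants, n_trials, experiment = 1,
                             population = population_params(),
                             cfg = game_config(), seed = NULL,
                             pursuit = TRUE,
                             controller = c("synthetic", "autopilot"),
                             keep_trajectories = c("inference", "all",
                                                   "none"),
                             inference_cap = 3) {
  controller <- match.arg(controller)
  keep_trajectories <- match.arg(keep_trajectories)
  if (!is.null(seed)) set.seed(seed)
  icfg <- cfg
  icfg$inference_time_cap <- min(inference_cap, cfg$inference_time_cap)

  params_list <- vector("list", n_participants)
  trial_rows <- vector("list", n_participants)
  traj_rows <- list()
  gaze_rows <- list()

  for (p in seq_len(n_participants)) {
    pars <- draw_participant(population)
    params_list[[p]] <- pars
    sched <- make_schedule(experiment, n_trials, cfg)
    feats <- matrix(NA_real_, n_trials, 15,
                    dimnames = list(NULL, feature_names()))
    rows <- sched
    rows$participant <- p
    rows$delta_f_prev <- dplyr::lag(sched$delta_f, default = 0)
    rows$choice <- NA_character_
    rows$p_boost <- NA_real_
    rows$decision_time <- NA_real_
    rows$inference_duration <- NA_real_
    rows$inference_capped <- NA
    rows$capture_time <- NA_real_
    rows$captured_by <- NA_character_
    rows$reward <- NA_real_

    for (i in seq_len(n_trials)) {
      inf <- run_inference_phase(sched$f_inference[i], icfg)
      feats[i, ] <- build_features(inf$trajectories, cfg)
      rows$inference_duration[i] <- inf$duration
      rows$inference_capped[i] <- inf$capped
      pb <- prob_boost(feats[i, ], rows$delta_f_prev[i], pars)
      rows$p_boost[i] <- pb
      rows$choice[i] <- if (rbinom(1, 1, pb) == 1) "boost" else "hinder"
      rows$decision_time[i] <-
        max(0.3, rnorm(1, pars$decision_time_mean, pars$decision_time_sd))

      if (keep_trajectories %in% c("inference", "all")) {
        tr <- inf$trajectories
        tr$participant <- p; tr$trial <- i; tr$phase_name <- "inference"
        traj_rows[[length(traj_rows) + 1L]] <- tr
      }

      if (pursuit) {
        pur <- run_pursuit_phase(sched$f_pursuit[i], rows$choice[i],
                                 controller = "autopilot", cfg = cfg,
                                 f_inference = sched$f_inference[i])
        ptr <- pur$trajectories
        gz <- simulate_gaze(ptr, sched$condition[i], pars, cfg)
        if (controller == "synthetic" && pars$control_noise > 0) {
          d_self <- sqrt((gz$gaze_x - ptr$play_x)^2 +
                           (gz$gaze_y - ptr$play_y)^2) / cfg$px_per_deg
          newp <- simulate_joystick(cbind(ptr$play_x, ptr$play_y), d_self,
                                    pars, cfg)
          ptr$play_x <- newp[, 1]
          ptr$play_y <- newp[, 2]
          # the perturbed player may touch the prey at a different frame
          ft_play <- first_touch_frame(ptr$play_x, ptr$play_y, ptr$prey_x,
                                       ptr$prey_y,
                                       cfg$capture_radius_pursuit)
          ft_opp <- if (pur$captured_by == "opponent")
            nrow(ptr) else NA_integer_
          ft <- suppressWarnings(min(ft_play, ft_opp, na.rm = TRUE))
          if (is.finite(ft)) {
            ptr <- ptr[seq_len(ft), ]
            gz <- gz[seq_len(ft), ]
            pur$captured_by <- if (!is.na(ft_play) &&
                                   (is.na(ft_opp) || ft_play <= ft_opp))
              "player" else "opponent"
            pur$capture_time <- ptr$t[ft]
          } else {
            pur$captured_by <- "none"
            pur$capture_time <- NA_real_
          }
        }
        rows$capture_time[i] <- pur$capture_time
        rows$captured_by[i] <- pur$captured_by
        rows$reward[i] <- score_trial(pur$capture_time, pur$captured_by,
                                      sched$f_pursuit[i], cfg)
        if (keep_trajectories == "all") {
          ptr2 <- ptr
          ptr2$participant <- p; ptr2$trial <- i
          ptr2$phase_name <- "pursuit"
          traj_rows[[length(traj_rows) + 1L]] <- ptr2
        }
        gz$participant <- p; gz$trial <- i
        gaze_rows[[length(gaze_rows) + 1L]] <- gz
      }
    }
    rows$choice_bin <- as.integer(rows$choice == "boost")
    rows$prev_reward <- dplyr::lag(rows$reward)
    trial_rows[[p]] <- dplyr::bind_cols(rows, tibble::as_tibble(feats))
  }

  trials <- dplyr::bind_rows(trial_rows) |>
    dplyr::relocate("participant")
  structure(
    list(
      trials = trials,
      trajectories = if (length(traj_rows)) dplyr::bind_rows(traj_rows)
                     else tibble::tibble(),
      gaze = if (length(gaze_rows)) dplyr::bind_rows(gaze_rows)
             else tibble::tibble(),
      params = params_list,
      population = population,
      config = cfg,
      experiment = experiment,
      seed = seed
    ),
    class = "pursuit_dataset"
  )
}

#' @export
print.pursuit_dataset <- function(x, ...) {
  cat("<pursuit_dataset> experiment", x$experiment, "\n")
  cat(" ", dplyr::n_distinct(x$trials$participant), "participants x",
      max(x$trials$trial), "trials =", nrow(x$trials), "rows\n")
  invisible(x)
}
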