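#' World state constructor
#'
#' A snapshot of the arena: prey, opponent and player positions in pixels,
#' plus a short prey position history (previous frames, most recent last)
#' used by the prey revisit rule (last 2 frames) and the autopilot
#' predictor (last 5 frames).
#'
#' @param prey,opponent,player length-2 numeric `(x, y)` in pixels.
#' @param prey_history matrix with columns x, y of previous prey positions
#'   (most recent last); may have zero rows.
#' @param time elapsed time in seconds.
#' @param cfg a [game_config()] used to check bounds.
#' @return A list of class `world_state`.
#' @export
world_state <- function(prey, opponent, player,
                        prey_history = matrix(numeric(0), ncol = 2),
                        time = 0, cfg = game_config()) {
  st <- structure(
    list(prey = as.numeric(prey), opponent = as.numeric(opponent),
         player = as.numeric(player),
         prey_history = matrix(as.numeric(prey_history), ncol = 2),
         time = time),
    class = "world_state"
  )
  for (agent in c("prey", "opponent", "player")) {
    p <- st[[agent]]
    if (p[1] < 0 || p[1] > cfg$arena_width || p[2] < 0 || p[2] > cfg$arena_height) {
      stop(agent, " position outside arena bounds")
    }
  }
  st
}

#' Random initial positions
#'
#' The prey is placed uniformly in the arena (with a wall margin); the
#' player and opponent are placed at a common distance drawn uniformly from
#' the 20 to 20.5 degree band, at independent random angles, so both
#' pursuers start exactly equidistant from the prey. Placements that leave
#' the arena or overlap each other are rejected and resampled.
#'
#' @param cfg a [game_config()].
#' @param max_attempts rejection-sampling cap before an error is raised
#'   (infeasible geometry, e.g. an arena smaller than the placement band).
#' @return A [world_state()].
#' @export
initialize_positions <- function(cfg = game_config(), max_attempts = 1000) {
  ppd <- cfg$px_per_deg
  m <- cfg$init_margin * ppd
  cr <- cfg$character_radius * ppd
  lo <- c(m, m)
  hi <- c(cfg$arena_width - m, cfg$arena_height - m)
  if (any(hi <= lo)) stop("arena too small for the placement margin")
  for (i in seq_len(max_attempts)) {
    prey <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    d <- runif(1, cfg$init_distance_min, cfg$init_distance_max) * ppd
    ang <- runif(2, 0, 2 * pi)
    play <- prey + d * c(cos(ang[1]), sin(ang[1]))
    oppo <- prey + d * c(cos(ang[2]), sin(ang[2]))
    ok <- all(c(play, oppo) >= cr) &&
      play[1] <= cfg$arena_width - cr && oppo[1] <= cfg$arena_width - cr &&
      play[2] <= cfg$arena_height - cr && oppo[2] <= cfg$arena_height - cr &&
      sqrt(sum((play - oppo)^2)) >= 2 * cr
    if (ok) return(world_state(prey, oppo, play, cfg = cfg))
  }
  stop("initialize_positions: no feasible placement after ", max_attempts,
       " attempts")
}

#' Candidate next positions for an agent
#'
#' Enumerates the 15 candidate positions, evenly spaced 24 degrees apart
#' and equidistant from the agent, and removes candidates that overlap a
#' border or another character. The candidate radius is the agent's speed
#' times the direction-decision horizon (see [game_config()]'s
#' `decision_horizon`); pass `horizon = 1 / cfg$frame_rate` for one-frame
#' candidates.
#'
#' @param state a [world_state()].
#' @param agent `"prey"` or `"opponent"`.
#' @param cfg a [game_config()].
#' @param phase `"inference"` or `"pursuit"` (sets the speed constants).
#' @param choice for the pursuit-phase opponent, `"boost"` or `"hinder"`.
#' @param horizon decision horizon in seconds (default from `cfg`).
#' @return A tibble with columns `x`, `y`, `index` (1-based angle index).
#'   If the agent is fully cornered the tibble has zero rows and attribute
#'   `cornered = TRUE`.
#' @export
candidate_positions <- function(state, agent = c("prey", "opponent"),
                                cfg = game_config(),
                                phase = c("inference", "pursuit"),
                                choice = "boost", horizon = NULL) {
  agent <- match.arg(agent)
  phase <- match.arg(phase)
  if (is.null(horizon)) horizon <- cfg$decision_horizon
  speed <- agent_speed(state, agent, cfg, phase, choice)
  step <- speed * cfg$px_per_deg * horizon
  pos <- state[[agent]]
  others <- switch(agent,
    prey = rbind(state$opponent, state$player),
    opponent = rbind(state$prey, state$player)
  )
  m <- cpp_candidates(pos[1], pos[2], step, others, engine_cfg(cfg))
  out <- tibble::as_tibble(m)
  attr(out, "cornered") <- nrow(out) == 0
  out
}

agent_speed <- function(state, agent, cfg, phase, choice) {
  if (agent == "prey") {
    mx <- if (phase == "inference") cfg$prey_max_speed else cfg$prey_pursuit_speed
    d_opp <- sqrt(sum((state$prey - state$opponent)^2)) / cfg$px_per_deg
    prey_speed(d_opp, cfg, max_speed = mx)
  } else {
    if (phase == "inference") cfg$opponent_inference_speed
    else if (choice == "boost") cfg$opponent_boost_speed
    else cfg$opponent_hinder_speed
  }
}

#' Prey speed as a function of opponent distance
#'
#' Full speed while the opponent is within the threat radius (25 deg), then
#' a logistic decay with distance that falls below 2% of the maximum at 50
#' degrees.
#'
#' @param distance distance to the opponent, degrees (vectorized).
#' @param cfg a [game_config()].
#' @param max_speed speed ceiling in deg/s; defaults to the inference-phase
#'   maximum.
#' @return Speed in deg/s.
#' @export
#' @examples
#' prey_speed(c(10, 30, 60))
prey_speed <- function(distance, cfg = game_config(),
                       max_speed = cfg$prey_max_speed) {
  if (any(distance < 0)) stop("distance must be non-negative")
  ifelse(distance <= cfg$threat_radius, max_speed,
         max_speed / (1 + exp(cfg$sigmoid_steepness *
                                (distance - cfg$sigmoid_center))))
}

#' One prey step
#'
#' Chooses the candidate minimizing `0.6 * escape + 0.4 * centrality`
#' (both min-max normalized across candidates), excluding positions the
#' prey visited in the previous two frames (proximity within half a step).
#'
#' @inheritParams candidate_positions
#' @return Length-2 numeric: the new prey position (px).
#' @export
prey_step <- function(state, cfg = game_config(),
                      phase = c("inference", "pursuit")) {
  phase <- match.arg(phase)
  mx <- if (phase == "inference") cfg$prey_max_speed else cfg$prey_pursuit_speed
  hist <- tail(state$prey_history, 2)
  cpp_prey_step(state$prey, hist, state$opponent, state$player, mx,
                engine_cfg(cfg))
}

#' One opponent step
#'
#' For every candidate position the opponent predicts the prey's next
#' position by running the prey policy with the candidate substituted as
#' the opponent position, then minimizes
#' `F * d_play + (1 - F) * d_oppo` measured from that predicted prey
#' position. `F = 1` herds the prey toward the player; `F = 0` intercepts.
#'
#' @inheritParams candidate_positions
#' @param F the opponent's hidden intention, in `[0, 1]`.
#' @return Length-2 numeric: the new opponent position (px).
#' @export
opponent_step <- function(state, F, cfg = game_config(),
                          phase = c("inference", "pursuit"),
                          choice = "boost") {
  phase <- match.arg(phase)
  stopifnot(F >= 0, F <= 1)
  speed <- agent_speed(state, "opponent", cfg, phase, choice)
  mx <- if (phase == "inference") cfg$prey_max_speed else cfg$prey_pursuit_speed
  hist <- tail(state$prey_history, 2)
  cpp_opponent_step(state$opponent, state$prey, hist, state$player,
                    F, speed, mx, engine_cfg(cfg))
}

#' One autopilot step for the player
#'
#' Aims at the prey position extrapolated 750 ms ahead from the prey's mean
#' per-frame displacement over the last five frames (or fewer when history
#' is shorter) and moves toward it at the given speed.
#'
#' @inheritParams candidate_positions
#' @param speed player speed in deg/s; defaults to the phase default.
#' @return Length-2 numeric: the new player position (px).
#' @export
autopilot_step <- function(state, cfg = game_config(),
                           phase = c("inference", "pursuit"),
                           speed = NULL) {
  phase <- match.arg(phase)
  if (is.null(speed)) {
    speed <- if (phase == "inference") cfg$player_speed_inference
             else cfg$player_speed_pursuit
  }
  hist <- tail(state$prey_history, cfg$autopilot_history)
  cpp_autopilot_step(state$player, hist, state$prey, speed, engine_cfg(cfg))
}

traj_tibble <- function(mat, frame_rate) {
  out <- tibble::as_tibble(mat)
  out$frame <- seq_len(nrow(out)) - 1L
  out$t <- out$frame / frame_rate
  dplyr::select(out, "frame", "t", "prey_x", "prey_y", "oppo_x", "oppo_y",
                "play_x", "play_y")
}

#' Run the inference phase
#'
#' Steps all three policies at the frame rate until a pursuer comes within
#' the inference capture radius (100 px) of the prey, or until the hard
#' time cap.
#'
#' @param F opponent intention in `[0, 1]`.
#' @param cfg a [game_config()].
#' @param state optional [world_state()]; drawn by [initialize_positions()]
#'   when missing (uses the R random number generator).
#' @return A list with `trajectories` (tibble: frame, t, prey/oppo/play x,
#'   y), `duration` (s), `captured_by` (`"player"`, `"opponent"` or
#'   `"none"`), and `capped` (hit the time cap).
#' @export
run_inference_phase <- function(F, cfg = game_config(), state = NULL) {
  stopifnot(F >= 0, F <= 1)
  if (is.null(state)) state <- initialize_positions(cfg)
  max_frames <- as.integer(round(cfg$inference_time_cap * cfg$frame_rate))
  res <- cpp_run_phase(state$prey, state$opponent, state$player,
                       F, cfg$prey_max_speed, cfg$opponent_inference_speed,
                       cfg$player_speed_inference, 0L,
                       matrix(0, 1, 2),
                       cfg$capture_radius_inference, max_frames,
                       engine_cfg(cfg))
  list(
    trajectories = traj_tibble(res$trajectory, cfg$frame_rate),
    duration = res$duration,
    captured_by = c("none", "player", "opponent")[res$captured + 1L],
    capped = res$captured == 0L
  )
}

#' Run the pursuit phase
#'
#' The opponent runs its intention policy at the boost (2.13 deg/s) or
#' hinder (1.32 deg/s) speed; the player is driven by the autopilot at the
#' accuracy-adjusted speed (see [adjust_player_speed()]), or replays a
#' supplied path. The phase ends when a pursuer touches the prey or at the
#' 15 s limit.
#'
#' @param F_pursuit opponent intention during pursuit, in `[0, 1]`.
#' @param choice `"boost"` or `"hinder"`.
#' @param controller `"autopilot"` or `"replay"`.
#' @param cfg a [game_config()].
#' @param state optional [world_state()].
#' @param f_inference inference-phase F used for the speed adjustment;
#'   defaults to `F_pursuit`.
#' @param player_speed override of the adjusted player speed, deg/s.
#' @param player_path for `controller = "replay"`, a matrix of per-frame
#'   player positions (px).
#' @return A list with `trajectories`, `capture_time` (s, `NA` if the prey
#'   escaped) and `captured_by`.
#' @export
run_pursuit_phase <- function(F_pursuit, choice = c("boost", "hinder"),
                              controller = c("autopilot", "replay"),
                              cfg = game_config(), state = NULL,
                              f_inference = F_pursuit, player_speed = NULL,
                              player_path = NULL) {
  choice <- match.arg(choice)
  controller <- match.arg(controller)
  stopifnot(F_pursuit >= 0, F_pursuit <= 1)
  if (is.null(state)) state <- initialize_positions(cfg)
  if (is.null(player_speed)) {
    player_speed <- adjust_player_speed(choice, f_inference, cfg = cfg)
  }
  opp_speed <- if (choice == "boost") cfg$opponent_boost_speed
               else cfg$opponent_hinder_speed
  max_frames <- as.integer(round(cfg$pursuit_time_limit * cfg$frame_rate))
  mode <- if (controller == "replay") 1L else 0L
  if (mode == 1L) {
    stopifnot(!is.null(player_path), nrow(player_path) >= max_frames)
  } else {
    player_path <- matrix(0, 1, 2)
  }
  res <- cpp_run_phase(state$prey, state$opponent, state$player,
                       F_pursuit, cfg$prey_pursuit_speed, opp_speed,
                       player_speed, mode, player_path,
                       cfg$capture_radius_pursuit, max_frames,
                       engine_cfg(cfg))
  list(
    trajectories = traj_tibble(res$trajectory, cfg$frame_rate),
    capture_time = if (res$captured == 0L) NA_real_ else res$duration,
    captured_by = c("none", "player", "opponent")[res$captured + 1L]
  )
}

#' Accuracy-adjusted player speed for the pursuit phase
#'
#' When the opponent's intention was fully predictable (`F` 0 or 1) and the
#' boost/hinder choice was correct, the player's speed rises to the prey's
#' pursuit maximum; when incorrect, the speed gap to the prey doubles. At
#' `F = 0.5` the default speed is kept regardless of choice; intermediate
#' `F` interpolates linearly in `|F - 0.5|`.
#'
#' @param choice `"boost"` or `"hinder"` (vectorized).
#' @param f_inference inference-phase F in `[0, 1]` (vectorized).
#' @param correct logical; when `NULL`, derived as boost for `F > 0.5` and
#'   hinder for `F < 0.5`.
#' @param cfg a [game_config()].
#' @return Player speed in deg/s.
#' @export
#' @examples
#' adjust_player_speed("boost", 1)    # correct at F = 1: prey max speed
#' adjust_player_speed("boost", 0.5)  # unchanged default
adjust_player_speed <- function(choice, f_inference, correct = NULL,
                                cfg = game_config()) {
  stopifnot(all(f_inference >= 0), all(f_inference <= 1))
  if (is.null(correct)) {
    correct <- (f_inference >= 0.5 & choice == "boost") |
               (f_inference <= 0.5 & choice == "hinder")
  }
  w <- 2 * abs(f_inference - 0.5)
  gap <- cfg$prey_pursuit_speed - cfg$player_speed_pursuit
  cfg$player_speed_pursuit + ifelse(correct, w * gap, -w * gap)
}

#' Score a trial
#'
#' Player captures earn 100 points at or under 2 s, falling linearly to 0
#' at the 15 s limit. When the opponent captures first the participant
#' keeps a share: the player-equivalent score times the opponent's F value
#' times 0.5. No capture scores 0.
#'
#' @param capture_time capture time in seconds, `NA` for no capture
#'   (vectorized).
#' @param captured_by `"player"`, `"opponent"` or `"none"` (vectorized).
#' @param f_pursuit opponent F during pursuit (vectorized).
#' @param cfg a [game_config()].
#' @return Points in `[0, 100]`.
#' @export
#' @examples
#' score_trial(8.5, "player", 0.5)            # 50
#' score_trial(4.6, "opponent", 0.2)          # 80 * 0.2 * 0.5 = 8
score_trial <- function(capture_time, captured_by, f_pursuit,
                        cfg = game_config()) {
  tmax <- cfg$pursuit_time_limit
  t0 <- cfg$score_max_time
  t <- pmin(pmax(capture_time, t0), tmax)
  base <- 100 * (tmax - t) / (tmax - t0)
  base[is.na(capture_time)] <- 0
  out <- dplyr::case_when(
    captured_by == "player" ~ base,
    captured_by == "opponent" ~ base * f_pursuit * cfg$opponent_share_factor,
    .default = 0
  )
  unname(out)
}
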