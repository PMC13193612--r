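#' Game configuration
#'
#' Builds the full constant set of the prey-pursuit task. All speeds and
#' radii are in degrees of visual angle per second (or degrees) and are
#' converted to pixels internally through `px_per_deg`; arena geometry and
#' the two capture radii are in pixels.
#'
#' The printed task constants are taken as authoritative per phase rather
#' than derived from one another: the prey flees at up to 1.95 deg/s during
#' the inference phase (130% of the inference-phase player default, 1.5)
#' and moves at up to 1.5 deg/s during pursuit (130% of the pursuit-phase
#' player default, 1.5/1.3). The opponent moves at 1.65 deg/s while
#' intentions are being observed, and 2.13 (boost) or 1.32 (hinder) deg/s
#' during pursuit.
#'
#' @param ... named overrides for any field listed below.
#'
#' @return A list of class `game_config` with fields:
#' \describe{
#'   \item{frame_rate}{Hz, default 60.}
#'   \item{arena_width, arena_height}{arena size in pixels (1920 x 1080).}
#'   \item{px_per_deg}{pixels per degree of visual angle; 40 approximates a
#'     24-inch 1080p display viewed at 60 cm.}
#'   \item{player_speed_inference, player_speed_pursuit}{player default
#'     speed per phase, deg/s.}
#'   \item{prey_max_speed, prey_pursuit_speed}{prey speed ceiling per phase,
#'     deg/s.}
#'   \item{opponent_inference_speed, opponent_boost_speed,
#'     opponent_hinder_speed}{opponent speed, deg/s.}
#'   \item{candidate_count, candidate_spacing}{15 candidate headings, 24
#'     degrees apart.}
#'   \item{escape_weight, centrality_weight}{prey cost mixture (0.6/0.4).}
#'   \item{threat_radius, threat_far}{deg; full prey speed inside
#'     `threat_radius`, near-zero beyond `threat_far`.}
#'   \item{sigmoid_center, sigmoid_steepness}{logistic decay of prey speed
#'     with opponent distance (centre 37.5 deg, 0.4 per deg) so that speed
#'     falls below 2% of max at 50 deg.}
#'   \item{capture_radius_inference}{px; the inference phase ends when a
#'     pursuer is this close to the prey (100 px).}
#'   \item{capture_radius_pursuit}{px; touching distance during pursuit.}
#'   \item{character_radius}{deg; avatar radius used for border and overlap
#'     filtering of candidate moves.}
#'   \item{pursuit_time_limit, score_max_time}{s; 15 and 2.}
#'   \item{inference_time_cap}{s; hard termination cap on the inference
#'     phase (the capture rule alone need not halt).}
#'   \item{opponent_share_factor}{share of the player-equivalent score paid
#'     out when the opponent captures (0.5).}
#'   \item{autopilot_lookahead, autopilot_history}{prediction horizon (s)
#'     and history (frames) of the autopilot controller.}
#'   \item{decision_horizon}{s; direction decisions evaluate the 15
#'     candidates at `speed * decision_horizon` from the agent, while the
#'     per-frame displacement stays `speed / frame_rate` along the chosen
#'     direction. At 60 Hz a one-frame candidate radius is sub-pixel, which
#'     makes the opponent's intention behaviorally invisible; 0.25 s
#'     restores the shepherd/intercept behaviors. Set it to
#'     `1/frame_rate` for the literal one-frame rule.}
#'   \item{init_distance_min, init_distance_max}{deg; initial
#'     pursuer-to-prey distance band (20 to 20.5).}
#'   \item{init_margin}{deg; prey placement margin from the walls.}
#' }
#' @export
#' @examples
#' cfg <- game_config()
#' cfg$prey_max_speed
game_config <- function(...) {
  cfg <- list(
    frame_rate = 60,
    arena_width = 1920,
    arena_height = 1080,
    px_per_deg = 40,
    player_speed_inference = 1.5,
    player_speed_pursuit = 1.5 / 1.3,
    prey_max_speed = 1.95,
    prey_pursuit_speed = 1.5,
    opponent_inference_speed = 1.65,
    opponent_boost_speed = 2.13,
    opponent_hinder_speed = 1.32,
    candidate_count = 15,
    candidate_spacing = 24,
    escape_weight = 0.6,
    centrality_weight = 0.4,
    threat_radius = 25,
    threat_far = 50,
    sigmoid_center = 37.5,
    sigmoid_steepness = 0.4,
    capture_radius_inference = 100,
    capture_radius_pursuit = 30,
    character_radius = 0.4,
    pursuit_time_limit = 15,
    score_max_time = 2,
    inference_time_cap = 15,
    opponent_share_factor = 0.5,
    autopilot_lookahead = 0.75,
    autopilot_history = 5,
    decision_horizon = 0.25,
    init_distance_min = 20,
    init_distance_max = 20.5,
    init_margin = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown game_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_game_config(structure(cfg, class = "game_config"))
}

validate_game_config <- function(cfg) {
  stopifnot(
    cfg$frame_rate > 0,
    cfg$px_per_deg > 0,
    abs(cfg$escape_weight + cfg$centrality_weight - 1) < 1e-12,
    cfg$candidate_count * cfg$candidate_spacing == 360,
    cfg$score_max_time > 0,
    cfg$score_max_time < cfg$pursuit_time_limit,
    cfg$init_distance_min <= cfg$init_distance_max
  )
  cfg
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Flat numeric list handed to the C++ core, with the character radius
# resolved to pixels.
engine_cfg <- function(cfg) {
  list(
    arena_width = cfg$arena_width,
    arena_height = cfg$arena_height,
    px_per_deg = cfg$px_per_deg,
    frame_rate = cfg$frame_rate,
    character_radius_px = cfg$character_radius * cfg$px_per_deg,
    escape_weight = cfg$escape_weight,
    centrality_weight = cfg$centrality_weight,
    candidate_count = as.integer(cfg$candidate_count),
    candidate_spacing = cfg$candidate_spacing,
    threat_radius = cfg$threat_radius,
    sigmoid_center = cfg$sigmoid_center,
    sigmoid_steepness = cfg$sigmoid_steepness,
    autopilot_lookahead = cfg$autopilot_lookahead,
    autopilot_history = as.integer(cfg$autopilot_history),
    decision_horizon = cfg$decision_horizon
  )
}
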