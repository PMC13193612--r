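# Independent brute-force re-implementations of the agent policies, written
# directly from their documented behavior. These deliberately share no code
# with the package's C++ engine.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_minmax <- function(v) {
  r <- max(v) - min(v)
  if (r > 0) (v - min(v)) / r else rep(0, length(v))
}

o_candidates <- function(pos, step, others, cfg) {
  cr <- cfg$character_radius * cfg$px_per_deg
  ang <- (seq_len(cfg$candidate_count) - 1) * cfg$candidate_spacing * pi / 180
  out <- NULL
  for (k in seq_along(ang)) {
    p <- pos + step * c(cos(ang[k]), sin(ang[k]))
    if (p[1] < cr || p[1] > cfg$arena_width - cr ||
        p[2] < cr || p[2] > cfg$arena_height - cr) next
    clash <- FALSE
    for (j in seq_len(nrow(others))) {
      if (o_dist(p, others[j, ]) < 2 * cr) { clash <- TRUE; break }
    }
    if (clash) next
    out <- rbind(out, c(p, k))
  }
  out  # columns x, y, angle index (1-based); NULL if cornered
}

o_prey_speed <- function(d_opp, max_speed, cfg) {
  if (d_opp <= cfg$threat_radius) max_speed
  else max_speed / (1 + exp(cfg$sigmoid_steepness * (d_opp - cfg$sigmoid_center)))
}

# Prey direction decision at the horizon scale; returns the chosen horizon
# candidate and the per-frame step position.
o_prey_choose <- function(prey, hist, opp, play, prey_max, cfg) {
  ppd <- cfg$px_per_deg
  sp <- o_prey_speed(o_dist(prey, opp) / ppd, prey_max, cfg) * ppd
  step_h <- sp * cfg$decision_horizon
  step_f <- sp / cfg$frame_rate
  if (step_h <= 0) return(list(choice = prey, frame_pos = prey, k = NA))
  cand <- o_candidates(prey, step_h, rbind(opp, play), cfg)
  if (is.null(cand)) return(list(choice = prey, frame_pos = prey, k = NA))
  esc <- cen <- numeric(nrow(cand))
  ctr <- c(cfg$arena_width, cfg$arena_height) / 2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1:2]
    esc[i] <- -((o_dist(p, play) - o_dist(prey, play)) +
                  (o_dist(p, opp) - o_dist(prey, opp)))
    cen[i] <- o_dist(p, ctr)
  }
  cost <- cfg$escape_weight * o_minmax(esc) +
    cfg$centrality_weight * o_minmax(cen)
  allowed <- rep(TRUE, nrow(cand))
  if (nrow(hist) > 0) {
    hist <- hist[max(1, nrow(hist) - 1):nrow(hist), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      for (h in seq_len(nrow(hist))) {
        if (o_dist(cand[i, 1:2], hist[h, ]) < step_f / 2) allowed[i] <- FALSE
      }
    }
  }
  if (!any(allowed)) allowed <- rep(TRUE, nrow(cand))
  best <- which(allowed)[which.min(cost[allowed])]
  k <- cand[best, 3]
  ang <- (k - 1) * cfg$candidate_spacing * pi / 180
  list(choice = cand[best, 1:2],
       frame_pos = prey + step_f * c(cos(ang), sin(ang)), k = k)
}

# Continuous prey prediction used inside the opponent's lookahead.
o_predict_prey <- function(prey, opp, play, prey_max, cfg) {
  ppd <- cfg$px_per_deg
  e <- c(0, 0)
  if (o_dist(prey, opp) > 0) e <- e + (prey - opp) / o_dist(prey, opp)
  if (o_dist(prey, play) > 0) e <- e + (prey - play) / o_dist(prey, play)
  en <- sqrt(sum(e^2))
  step_h <- o_prey_speed(o_dist(prey, opp) / ppd, prey_max, cfg) * ppd *
    cfg$decision_horizon
  if (en < 1e-12) prey else prey + step_h * e / en
}

o_opponent_step <- function(opp, prey, play, F, opp_speed, prey_max, cfg) {
  ppd <- cfg$px_per_deg
  step_h <- opp_speed * ppd * cfg$decision_horizon
  step_f <- opp_speed * ppd / cfg$frame_rate
  cand <- o_candidates(opp, step_h, rbind(prey, play), cfg)
  if (is.null(cand)) return(opp)
  dplay <- doppo <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    q <- o_predict_prey(prey, cand[i, 1:2], play, prey_max, cfg)
    dplay[i] <- o_dist(q, play)
    doppo[i] <- o_dist(q, cand[i, 1:2])
  }
  cost <- F * o_minmax(dplay) + (1 - F) * o_minmax(doppo)
  k <- cand[which.min(cost), 3]
  ang <- (k - 1) * cfg$candidate_spacing * pi / 180
  opp + step_f * c(cos(ang), sin(ang))
}

o_autopilot_step <- function(play, prey, prey_hist, speed, cfg) {
  ppd <- cfg$px_per_deg
  disp <- c(0, 0)
  nh <- nrow(prey_hist)
  if (nh > 0) {
    k <- min(nh, cfg$autopilot_history)
    disp <- (prey - prey_hist[nh - k + 1, ]) / k
  }
  target <- prey + disp * cfg$autopilot_lookahead * cfg$frame_rate
  step <- speed * ppd / cfg$frame_rate
  d <- o_dist(play, target)
  out <- if (d <= step || d == 0) target else play + step * (target - play) / d
  cr <- cfg$character_radius * ppd
  pmin(pmax(out, cr), c(cfg$arena_width - cr, cfg$arena_height - cr))
}

# A random in-bounds world state away from walls.
random_state <- function(cfg, margin = 3) {
  m <- margin * cfg$px_per_deg
  rp <- function() c(runif(1, m, cfg$arena_width - m),
                     runif(1, m, cfg$arena_height - m))
  repeat {
    prey <- rp(); opp <- rp(); play <- rp()
    dmin <- 2.5 * cfg$character_radius * cfg$px_per_deg
    if (o_dist(prey, opp) > dmin && o_dist(prey, play) > dmin &&
        o_dist(opp, play) > dmin) break
  }
  world_state(prey, opp, play, cfg = cfg)
}
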