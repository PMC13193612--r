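cfg <- game_config()
ppd <- cfg$px_per_deg

test_that("config invariants are enforced", {
  expect_error(game_config(escape_weight = 0.7), "escape_weight")
  expect_error(game_config(candidate_count = 14), "candidate")
  expect_error(game_config(score_max_time = 20))
  expect_error(game_config(nonsense = 1), "unknown")
  expect_equal(cfg$escape_weight + cfg$centrality_weight, 1)
  expect_equal(cfg$candidate_count * cfg$candidate_spacing, 360)
})

test_that("candidate enumeration: 15 positions, 24 degrees apart, filtered", {
  st <- world_state(c(960, 540), c(200, 200), c(1700, 900), cfg = cfg)
  cand <- candidate_positions(st, "prey", cfg)
  expect_equal(nrow(cand), 15)
  r <- sqrt((cand$x - 960)^2 + (cand$y - 540)^2)
  expect_true(all(abs(r - r[1]) < 1e-9))
  ang <- sort((atan2(cand$y - 540, cand$x - 960) * 180 / pi) %% 360)
  expect_equal(diff(ang), rep(24, 14), tolerance = 1e-8)

  # flush against the left wall: all x < wall candidates removed
  stw <- world_state(c(cfg$character_radius * ppd, 540), c(600, 200),
                     c(1700, 900), cfg = cfg)
  cw <- candidate_positions(stw, "prey", cfg)
  expect_lt(nrow(cw), 15)
  expect_true(all(cw$x >= cfg$character_radius * ppd))

  # equals an independent enumeration with the same filter
  set.seed(1)
  for (i in 1:20) {
    st <- random_state(cfg)
    speed <- prey_speed(o_dist(st$prey, st$opponent) / ppd, cfg)
    ours <- candidate_positions(st, "prey", cfg)
    theirs <- o_candidates(st$prey, speed * ppd * cfg$decision_horizon,
                           rbind(st$opponent, st$player), cfg)
    expect_equal(as.matrix(ours[, c("x", "y")]),
                 unname(theirs[, 1:2, drop = FALSE]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("prey speed: max when threatened, near zero far away, monotone", {
  expect_equal(prey_speed(10, cfg), 1.95)
  expect_lt(prey_speed(60, cfg), 0.04)
  expect_lt(prey_speed(50, cfg), 0.02 * 1.95)
  grid <- prey_speed(seq(0, 80, by = 0.5), cfg)
  expect_true(all(diff(grid) <= 1e-12))
  expect_error(prey_speed(-1, cfg), "non-negative")
})

test_that("prey step matches the brute-force cost argmin", {
  set.seed(2)
  for (i in 1:60) {
    st <- random_state(cfg)
    ours <- prey_step(st, cfg)
    oracle <- o_prey_choose(st$prey, st$prey_history, st$opponent,
                            st$player, cfg$prey_max_speed, cfg)
    expect_equal(ours, oracle$frame_pos, tolerance = 1e-9)
  }
})

test_that("prey flees a single nearby pursuer to the opposite half-plane", {
  st <- world_state(c(960, 540), c(960 + 5 * ppd, 540),
                    c(960 + 5 * ppd, 540 + 1), cfg = cfg)
  np <- prey_step(st, cfg)
  expect_lt(np[1], 960)  # moves west away from the eastern pursuers
})

test_that("prey barely moves when both pursuers are far", {
  # a coarser pixel scale makes the arena large enough in degrees
  cfg2 <- game_config(px_per_deg = 18)
  st <- world_state(c(960, 540), c(30, 30), c(1890, 1050), cfg = cfg2)
  expect_gt(o_dist(st$prey, st$opponent) / 18, cfg2$threat_far)
  np <- prey_step(st, cfg2)
  expect_lt(o_dist(np, st$prey) / 18, 0.0007)  # < 2% of max per frame
})

test_that("opponent step matches the brute-force F-weighted argmin", {
  set.seed(3)
  for (F in c(0, 0.25, 0.5, 0.8, 1)) {
    for (i in 1:20) {
      st <- random_state(cfg)
      ours <- opponent_step(st, F, cfg)
      oracle <- o_opponent_step(st$opponent, st$prey, st$player, F,
                                cfg$opponent_inference_speed,
                                cfg$prey_max_speed, cfg)
      expect_equal(ours, oracle, tolerance = 1e-9)
    }
  }
})

test_that("opponent intention shapes predicted prey distances", {
  # F = 1 steps reduce the predicted prey-player distance more than F = 0
  # steps, and conversely for the prey-opponent distance
  set.seed(4)
  red_play <- red_oppo <- matrix(NA, 100, 2)
  for (i in 1:100) {
    st <- random_state(cfg)
    for (j in 1:2) {
      F <- c(1, 0)[j]
      np <- opponent_step(st, F, cfg)
      q0 <- o_predict_prey(st$prey, st$opponent, st$player,
                           cfg$prey_max_speed, cfg)
      q1 <- o_predict_prey(st$prey, np, st$player, cfg$prey_max_speed, cfg)
      red_play[i, j] <- o_dist(q0, st$player) - o_dist(q1, st$player)
      red_oppo[i, j] <- o_dist(q0, st$opponent) - o_dist(q1, np)
    }
  }
  expect_gt(mean(red_play[, 1]), mean(red_play[, 2]))
  expect_gt(mean(red_oppo[, 2]), mean(red_oppo[, 1]))
})

test_that("autopilot extrapolates prey motion and matches its oracle", {
  # stationary prey: heads straight at it
  hist <- matrix(rep(c(500, 500), 5), ncol = 2, byrow = TRUE)
  st <- world_state(c(500, 500), c(200, 900), c(900, 500),
                    prey_history = hist, cfg = cfg)
  np <- autopilot_step(st, cfg)
  expect_equal(np[2], 500, tolerance = 1e-9)
  expect_lt(np[1], 900)

  # constant northward velocity: target is 0.75 s ahead
  v <- 2  # px per frame
  hist <- cbind(500, 500 - v * (5:1))
  st <- world_state(c(500, 500), c(200, 900), c(500, 900),
                    prey_history = hist, cfg = cfg)
  np <- autopilot_step(st, cfg)
  target <- c(500, 500 + v * 0.75 * cfg$frame_rate)
  dir_expected <- (target - st$player) / o_dist(target, st$player)
  dir_actual <- (np - st$player) / o_dist(np, st$player)
  expect_equal(dir_actual, dir_expected, tolerance = 1e-9)

  # random-history oracle equivalence
  set.seed(5)
  for (i in 1:20) {
    st <- random_state(cfg)
    st$prey_history <- st$prey + matrix(rnorm(10, 0, 5), 5, 2)
    np <- autopilot_step(st, cfg)
    ora <- o_autopilot_step(st$player, st$prey,
                            tail(st$prey_history, 5),
                            cfg$player_speed_inference, cfg)
    expect_equal(np, ora, tolerance = 1e-9)
  }
})

test_that("initial placement puts both pursuers equidistant in the band", {
  set.seed(6)
  d <- replicate(300, {
    st <- initialize_positions(cfg)
    c(o_dist(st$player, st$prey), o_dist(st$opponent, st$prey)) / ppd
  })
  expect_true(all(d >= 20 & d <= 20.5))
  expect_equal(d[1, ], d[2, ], tolerance = 1e-9)
  # the band is covered
  expect_lt(min(d), 20.1)
  expect_gt(max(d), 20.4)
  # degenerate arena: infeasible geometry errors out
  tiny <- game_config(arena_width = 400, arena_height = 300)
  expect_error(initialize_positions(tiny), "feasible|small")
})

test_that("inference phase terminates at the capture radius or the cap", {
  set.seed(7)
  for (i in 1:5) {
    r <- run_inference_phase(runif(1), cfg)
    tr <- r$trajectories
    dp <- sqrt((tr$play_x - tr$prey_x)^2 + (tr$play_y - tr$prey_y)^2)
    do <- sqrt((tr$oppo_x - tr$prey_x)^2 + (tr$oppo_y - tr$prey_y)^2)
    hit <- which(dp <= cfg$capture_radius_inference |
                   do <= cfg$capture_radius_inference)
    if (r$captured_by == "none") {
      expect_true(r$capped)
      expect_equal(r$duration, cfg$inference_time_cap)
      expect_length(hit, 0)
    } else {
      # post-hoc scan of the log agrees with the engine's stop frame
      expect_equal(hit[1] - 1L, max(tr$frame))
      expect_equal(r$duration, max(tr$t))
    }
    expect_gt(r$duration, 0)
  }
})

test_that("identical seed and config give bit-identical trial logs", {
  run <- function() {
    set.seed(99)
    r <- run_inference_phase(0.42, cfg)
    r$trajectories
  }
  expect_identical(run(), run())
})

test_that("pursuit phase speeds, capture scan and stationary-prey capture", {
  # hinder: opponent per-frame step length is 1.32 deg/s / frame_rate
  set.seed(8)
  st <- initialize_positions(cfg)
  r <- run_pursuit_phase(0.5, "hinder", cfg = cfg, state = st)
  tr <- r$trajectories
  step <- sqrt(diff(tr$oppo_x)^2 + diff(tr$oppo_y)^2) / ppd * cfg$frame_rate
  expect_equal(max(step), cfg$opponent_hinder_speed, tolerance = 1e-6)

  # post-hoc first-touch scan agrees with the runner
  if (r$captured_by != "none") {
    dp <- sqrt((tr$play_x - tr$prey_x)^2 + (tr$play_y - tr$prey_y)^2)
    do <- sqrt((tr$oppo_x - tr$prey_x)^2 + (tr$oppo_y - tr$prey_y)^2)
    hit <- which(dp <= cfg$capture_radius_pursuit |
                   do <= cfg$capture_radius_pursuit)
    expect_equal(hit[1] - 1L, max(tr$frame))
  }

  # a frozen prey near the player is caught well before the limit
  frozen <- game_config(prey_pursuit_speed = 0)
  st2 <- world_state(c(960, 540), c(200, 900), c(960, 540 - 8 * ppd),
                     cfg = frozen)
  r2 <- run_pursuit_phase(0, "hinder", cfg = frozen, state = st2,
                          player_speed = frozen$player_speed_pursuit)
  expect_equal(r2$captured_by, "player")
  expect_lt(r2$capture_time, frozen$pursuit_time_limit / 2)
})

test_that("player speed adjustment: endpoints, midpoint, interpolation", {
  expect_equal(adjust_player_speed("boost", 1, cfg = cfg),
               cfg$prey_pursuit_speed)
  expect_equal(adjust_player_speed("hinder", 0, cfg = cfg),
               cfg$prey_pursuit_speed)
  expect_equal(adjust_player_speed("boost", 0.5, cfg = cfg),
               cfg$player_speed_pursuit)
  expect_equal(adjust_player_speed("hinder", 0.5, cfg = cfg),
               cfg$player_speed_pursuit)
  # incorrect at an endpoint doubles the speed gap to the prey
  gap <- cfg$prey_pursuit_speed - cfg$player_speed_pursuit
  expect_equal(adjust_player_speed("hinder", 1, cfg = cfg),
               cfg$prey_pursuit_speed - 2 * gap)
  # F = 0.75 correct: midway between no change and the full change
  expect_equal(adjust_player_speed("boost", 0.75, cfg = cfg),
               cfg$player_speed_pursuit + gap / 2)
})

test_that("scoring follows the printed worked examples and is monotone", {
  expect_equal(score_trial(2, "player", 0.5), 100)
  expect_equal(score_trial(1, "player", 0.5), 100)
  expect_equal(score_trial(8.5, "player", 0.5), 50)
  expect_equal(score_trial(15, "player", 0.5), 0)
  expect_equal(score_trial(NA, "none", 0.5), 0)
  # opponent capture: player-equivalent 80 points at F = 0.2 pays 8
  t80 <- 15 - 0.8 * 13
  expect_equal(score_trial(t80, "player", 0.2), 80)
  expect_equal(score_trial(t80, "opponent", 0.2), 8)
  # piecewise linear, non-increasing, bounded
  ts <- seq(0, 15, by = 0.25)
  s <- score_trial(ts, rep("player", length(ts)), 0.5)
  expect_true(all(diff(s) <= 1e-9))
  expect_true(all(s >= 0 & s <= 100))
  expect_true(all(score_trial(ts, rep("opponent", length(ts)), 1) <=
                    0.5 * s + 1e-9))
})

test_that("boosting a cooperative opponent pays more than hindering it", {
  set.seed(10)
  mean_reward <- function(F, choice, n = 60) {
    mean(replicate(n, {
      r <- run_pursuit_phase(F, choice, cfg = cfg, f_inference = F)
      score_trial(r$capture_time, r$captured_by, F, cfg)
    }))
  }
  expect_gt(mean_reward(0.95, "boost"), mean_reward(0.95, "hinder"))
  expect_gt(mean_reward(0.05, "hinder"), mean_reward(0.05, "boost"))
})
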