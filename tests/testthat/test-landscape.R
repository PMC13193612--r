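cfg <- game_config()

test_that("trajectory features: constants, oracle recompute, invariance", {
  # static agents: every bin equals the static pairwise distance
  n <- 120
  traj <- tibble::tibble(
    frame = 0:(n - 1), t = (0:(n - 1)) / 60,
    prey_x = 500, prey_y = 500, oppo_x = 900, oppo_y = 500,
    play_x = 500, play_y = 800
  )
  x <- build_features(traj, cfg)
  ppd <- cfg$px_per_deg
  expect_equal(unname(x[1:5]), rep(400 / ppd, 5))
  expect_equal(unname(x[6:10]), rep(300 / ppd, 5))
  expect_equal(unname(x[11:15]), rep(500 / ppd, 5))

  # frame-wise recomputation oracle on a random trajectory
  set.seed(40)
  rt <- dplyr::mutate(traj,
                      prey_x = 500 + cumsum(rnorm(n)),
                      prey_y = 500 + cumsum(rnorm(n)),
                      oppo_x = 900 + cumsum(rnorm(n)),
                      oppo_y = 520 + cumsum(rnorm(n)),
                      play_x = 450 + cumsum(rnorm(n)),
                      play_y = 820 + cumsum(rnorm(n)))
  x2 <- build_features(rt, cfg)
  mat <- as.matrix(rt[, 3:8])
  bw <- 12
  oracle <- c()
  pairs <- list(c(1, 3), c(1, 5), c(3, 5))
  for (p in pairs) {
    d <- sqrt((mat[, p[1]] - mat[, p[2]])^2 +
                (mat[, p[1] + 1] - mat[, p[2] + 1])^2) / ppd
    for (b in 1:5) {
      idx <- (n - (5 - b + 1) * bw + 1):(n - (5 - b) * bw)
      oracle <- c(oracle, mean(d[idx]))
    }
  }
  expect_equal(as.numeric(x2), oracle, tolerance = 1e-9)

  # translating every agent leaves the features unchanged
  sh <- dplyr::mutate(rt, dplyr::across(dplyr::ends_with("_x"), ~ .x + 37),
                      dplyr::across(dplyr::ends_with("_y"), ~ .x - 12))
  expect_equal(build_features(sh, cfg), x2, tolerance = 1e-9)

  # short trajectories flag truncation
  x3 <- build_features(rt[1:30, ], cfg)
  expect_true(attr(x3, "truncated"))
})

test_that("autoregressive logistic fit: null data, MLE dominance", {
  set.seed(41)
  n <- 400
  d <- tibble::tibble(!!!setNames(
    lapply(feature_names(), function(nm) rnorm(n, 15, 3)),
    feature_names()))
  d$delta_f_prev <- runif(n, -0.45, 0.45)
  d$choice_bin <- rbinom(n, 1, 0.5)
  m <- fit_autoregressive_logit(d)
  expect_true(m$converged)
  expect_gte(m$loglik, m$loglik_null - 1e-9)
  # all coefficients within ~2 SE of zero for independent choices
  td <- tidy(m)
  expect_true(mean(abs(td$estimate[-1] / td$std.error[-1]) < 2.5) > 0.9)
  expect_equal(nrow(td), 17)
})

test_that("separation triggers the ridge-stabilized refit", {
  set.seed(42)
  n <- 80
  d <- tibble::tibble(!!!setNames(
    lapply(feature_names(), function(nm) rnorm(n, 15, 3)),
    feature_names()))
  d$delta_f_prev <- runif(n, -0.45, 0.45)
  d$choice_bin <- as.integer(d$d_po_t1 > 15)  # perfectly separable
  m <- suppressWarnings(fit_autoregressive_logit(d))
  expect_true(m$ridged)
  expect_true(all(is.finite(c(m$beta0, m$beta_t, m$beta_hys))))
})

test_that("inferred time series: constant model, range, fit consistency", {
  ds <- small_dataset()
  models <- small_models()
  traj <- ds$trajectories |>
    dplyr::filter(participant == 1, trial == 5,
                  phase_name == "inference")
  row <- ds$trials[ds$trials$participant == 1 & ds$trials$trial == 5, ]

  # feature-independent model is flat at logistic(beta0 + hys * dFprev)
  m0 <- structure(list(beta0 = 0.3, beta_t = setNames(rep(0, 15),
                                                      feature_names()),
                       beta_hys = 2), class = "inference_model")
  ts0 <- infer_timeseries(m0, traj, delta_f_prev = -0.4, cfg = cfg)
  expect_equal(ts0$f_hat, rep(plogis(0.3 - 0.8), nrow(traj)))

  m <- models[[1]]
  ts <- infer_timeseries(m, traj, row$delta_f_prev, cfg)
  expect_true(all(ts$f_hat >= 0 & ts$f_hat <= 1))
  expect_equal(nrow(ts), nrow(traj))
  # final frame equals the trial-level model prediction
  x <- build_features(traj, cfg)
  eta <- m$beta0 + sum(m$beta_t * x) + m$beta_hys * row$delta_f_prev
  expect_equal(ts$f_hat[nrow(ts)], plogis(eta), tolerance = 1e-9)
  expect_true(ts$truncated[1])
  expect_false(ts$truncated[nrow(ts)])
})

test_that("phase portrait: constructed attractor, constants, grouping oracle", {
  # exponential relaxation toward 0.5 from both sides
  fr <- 60
  t <- 0:300
  s1 <- 0.5 + 0.45 * exp(-t / 80)
  s2 <- 0.5 - 0.45 * exp(-t / 80)
  d <- tibble::tibble(trial = rep(1:2, each = length(t)),
                      f_hat = c(s1, s2))
  pp <- phase_portrait(d, frame_rate = fr, min_frames = 1)
  expect_true(all(pp$g[pp$center < 0.45] > 0, na.rm = TRUE))
  expect_true(all(pp$g[pp$center > 0.55] < 0, na.rm = TRUE))

  # constant series: zero drift in its bin
  dc <- tibble::tibble(trial = 1, f_hat = rep(0.31, 100))
  ppc <- phase_portrait(dc, min_frames = 1)
  expect_equal(ppc$g[!is.na(ppc$g)], 0)

  # binned means equal a brute-force grouping
  set.seed(43)
  dr <- tibble::tibble(trial = rep(1:5, each = 50),
                       f_hat = runif(250))
  ppr <- phase_portrait(dr, min_frames = 1)
  br <- dr |>
    dplyr::group_by(trial) |>
    dplyr::mutate(dfdt = (dplyr::lead(f_hat) - f_hat) * 60) |>
    dplyr::filter(!is.na(dfdt)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin = pmin(pmax(findInterval(
      f_hat, seq(0, 1, length.out = 21), rightmost.closed = TRUE), 1), 20))
  agg <- tapply(br$dfdt, factor(br$bin, levels = 1:20), mean)
  expect_equal(ppr$g, unname(as.numeric(agg)))
})

test_that("energy landscape: harmonic potential, degenerate and abs modes", {
  x <- seq(0.025, 0.975, by = 0.05)
  pp <- tibble::tibble(center = x, g = -2 * (x - 0.4), n = 100L)
  ls <- energy_landscape(pp, mode = "signed")
  # quadratic with the minimum at the drift zero
  fp <- fixed_point(ls)
  expect_equal(fp$order, 2)
  expect_equal(fp$fixed_point, 0.4, tolerance = 1e-3)
  expect_equal(min(ls$U_norm), 0)
  expect_equal(max(ls$U_norm), 1)

  # zero drift: degenerate flat potential
  pp0 <- tibble::tibble(center = x, g = 0, n = 100L)
  ls0 <- energy_landscape(pp0)
  expect_true(attr(ls0, "degenerate"))

  # printed |g| mode is monotone non-decreasing for any drift
  set.seed(44)
  ppr <- tibble::tibble(center = x, g = rnorm(20), n = 100L)
  lsa <- energy_landscape(ppr, mode = "printed_abs")
  expect_true(all(diff(lsa$U) >= -1e-12))

  expect_error(energy_landscape(tibble::tibble(center = x,
                                               g = c(1, 2, rep(NA, 18)))),
               "fewer than 3")
})

test_that("fixed point: AIC selection, noise robustness, boundary flag", {
  x <- seq(0.025, 0.975, by = 0.05)
  # noiseless quadratic: order 2 wins, vertex recovered
  U <- (x - 0.4)^2
  ls <- structure(tibble::tibble(center = x, g = NA, U = U,
                                 U_norm = (U - min(U)) / diff(range(U))),
                  class = c("energy_landscape", "tbl_df", "tbl", "data.frame"))
  fp <- fixed_point(ls)
  expect_equal(fp$order, 2)
  expect_equal(fp$fixed_point, 0.4, tolerance = 1e-3)
  expect_false(fp$boundary)

  # 1% noise: within 0.05 of the vertex across replicates
  set.seed(45)
  errs <- replicate(100, {
    Un <- U + rnorm(20, 0, 0.01 * diff(range(U)))
    lsn <- ls; lsn$U <- Un
    abs(fixed_point(lsn)$fixed_point - 0.4)
  })
  expect_lt(max(errs), 0.05)

  # monotone potential: boundary minimum, flagged
  lsm <- ls; lsm$U <- 2 * x + 0.3
  fpm <- fixed_point(lsm)
  expect_true(fpm$boundary)
  expect_equal(fpm$fixed_point, min(x), tolerance = 1e-6)
})

test_that("basin geometry: closed form, linear scaling, side-slope oracle", {
  x <- seq(0.025, 0.975, by = 0.05)
  U <- (x - 0.5)^2
  ls <- structure(tibble::tibble(center = x, g = NA, U = U,
                                 U_norm = (U - min(U)) / diff(range(U))),
                  class = c("energy_landscape", "tbl_df", "tbl", "data.frame"))
  geo <- basin_geometry(ls)
  expect_equal(geo$depth, max(U) - min(U))
  expect_equal(abs(geo$slope_left), abs(geo$slope_right), tolerance = 1e-6)

  ls2 <- ls; ls2$U <- 2 * U
  geo2 <- basin_geometry(ls2)
  expect_equal(geo2$depth, 2 * geo$depth)
  expect_equal(geo2$steepness, 2 * geo$steepness, tolerance = 1e-9)

  # asymmetric cubic: steepness equals the larger regression side slope
  U3 <- 0.2 * (x - 0.3)^2 + 0.5 * (x - 0.3)^3 + 0.05
  ls3 <- ls; ls3$U <- U3
  fp3 <- fixed_point(ls3)
  geo3 <- basin_geometry(ls3, fp3)
  side <- function(xs) unname(coef(lm(
    pursuitlab:::poly_eval(fp3$coefficients, xs) ~ xs))[2])
  sl <- side(x[x <= fp3$fixed_point])
  sr <- side(x[x >= fp3$fixed_point])
  expect_equal(geo3$steepness, max(abs(c(sl, sr))), tolerance = 1e-9)

  # fixed points are invariant to affine rescaling of U
  ls4 <- ls3; ls4$U <- 3 * U3 + 10
  expect_equal(fixed_point(ls4)$fixed_point, fp3$fixed_point,
               tolerance = 1e-6)
})

test_that("signed-mode landscapes recover a generative attractor", {
  # mean-reverting series around 0.35: fixed point within bin resolution
  set.seed(46)
  sims <- purrr::map_dfr(1:30, function(i) {
    x <- numeric(200); x[1] <- runif(1, 0.1, 0.6)
    for (t in 2:200) {
      x[t] <- x[t - 1] + 0.06 * (0.35 - x[t - 1]) + rnorm(1, 0, 0.02)
    }
    tibble::tibble(trial = i, f_hat = pmin(pmax(x, 0), 1))
  })
  pp <- phase_portrait(sims)
  ls <- energy_landscape(pp)
  fp <- fixed_point(ls)
  expect_lt(abs(fp$fixed_point - 0.35), 0.06)
})

test_that("condition landscapes separate constructed attractors", {
  # two conditions with different attractors, two participants
  set.seed(47)
  mk <- function(part, cond, a, n_tr) {
    purrr::map_dfr(seq_len(n_tr), function(i) {
      x <- numeric(150); x[1] <- runif(1, max(0, a - 0.25), min(1, a + 0.25))
      for (t in 2:150) x[t] <- x[t - 1] + 0.05 * (a - x[t - 1]) +
          rnorm(1, 0, 0.02)
      tibble::tibble(participant = part, trial = i + 1000 * (cond == "b"),
                     cond = cond, f_hat = pmin(pmax(x, 0), 1))
    })
  }
  d <- dplyr::bind_rows(
    mk(1, "a", 0.35, 12), mk(1, "b", 0.6, 12),
    mk(2, "a", 0.32, 12), mk(2, "b", 0.63, 12)
  )
  cl <- condition_landscapes(d, groups = "cond")
  fa <- cl$fixed_point[cl$cond == "a"]
  fb <- cl$fixed_point[cl$cond == "b"]
  expect_lt(abs(fa - 0.34), 0.08)
  expect_lt(abs(fb - 0.61), 0.08)
  per <- attr(cl, "per_participant")
  expect_equal(nrow(per), 4)
  expect_true(all(per$fixed_point[per$cond == "a"] <
                    per$fixed_point[per$cond == "b"]))
})
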