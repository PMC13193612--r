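tiny_cfg <- rnn_config(hidden_units = 5L, seq_len = 4L, step1_trials = 8L,
                       step1_epochs = 5L, augment_rotations = FALSE)

rand_X <- function(B, TT, I = 6) array(rnorm(B * I * TT, 0, 0.3),
                                       c(B, I, TT))

test_that("backpropagation matches numerical gradients", {
  set.seed(60)
  net <- init_rnn(tiny_cfg)
  B <- 3; TT <- 4
  X <- rand_X(B, TT)
  y <- runif(B)
  loss_of <- function(net) {
    p <- pursuitlab:::lstm_forward(net, X)$pred
    sum((p - y)^2)
  }
  fwd <- pursuitlab:::lstm_forward(net, X, keep_cache = TRUE)
  grads <- pursuitlab:::lstm_backward(net, fwd, 2 * (fwd$pred - y))
  eps <- 1e-6
  for (nm in c("Wx", "Wh", "b", "Wy", "by")) {
    g_num <- net[[nm]] * 0
    idx <- seq_along(net[[nm]])
    if (length(idx) > 40) idx <- sample(idx, 40)
    for (i in idx) {
      np <- net; np[[nm]][i] <- np[[nm]][i] + eps
      nm_ <- net; nm_[[nm]][i] <- nm_[[nm]][i] - eps
      g_num[i] <- (loss_of(np) - loss_of(nm_)) / (2 * eps)
    }
    expect_equal(as.numeric(grads[[nm]])[idx], as.numeric(g_num)[idx],
                 tolerance = 1e-5)
  }
})

test_that("step 1 fits a separable toy set and beats the mean predictor", {
  set.seed(61)
  B <- 40; TT <- 6
  y <- rep(c(0, 1), each = B / 2)
  X <- rand_X(B, TT)
  X[y == 1, 3, ] <- X[y == 1, 3, ] + 1  # grossly different trajectories
  cfgt <- rnn_config(hidden_units = 8L, seq_len = TT, step1_epochs = 120L,
                     augment_rotations = FALSE)
  s1 <- rnn_train_step1(X, y, cfgt)
  expect_lt(s1$mse, 0.05)
  expect_lt(s1$mse, var(y))  # beats the constant-predictor baseline
  # output recentring makes the training-set bias vanish
  expect_equal(mean(pursuitlab:::lstm_forward(s1$net, X)$pred - y), 0,
               tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  B <- 10; TT <- 4
  run <- function() {
    set.seed(62)
    X <- rand_X(B, TT)
    y <- runif(B)
    rnn_train_step1(X, y, tiny_cfg)$net
  }
  expect_identical(run(), run())
})

test_that("step 2: beta path, thresholds, freeze contract", {
  set.seed(63)
  net <- init_rnn(tiny_cfg)
  B <- 30; TT <- 4
  X <- rand_X(B, TT)
  # force all errors negative: Loss+ is empty, beta must rise to 0.9
  y <- pursuitlab:::lstm_forward(net, X)$pred + 0.5
  cfg2 <- tiny_cfg; cfg2$step2_epoch_cap <- 100L
  before <- net
  st <- rnn_train_step2(net, X, y, cfg2)
  expect_equal(st$classification, "help_sensitive")
  expect_lt(st$beta_bet, 0.1)
  # beta starts from its neutral initial value
  expect_lt(abs(st$trace$beta_bet[1] - (0.5 - cfg2$lr)), 0.02)
  # recurrent/output parameters of the base net are untouched
  expect_identical(net, before)
  expect_false(identical(st$Wx, net$Wx))

  # mirrored targets drive beta the other way
  y2 <- pursuitlab:::lstm_forward(net, X)$pred - 0.5
  st2 <- rnn_train_step2(net, X, y2, cfg2)
  expect_equal(st2$classification, "betrayal_sensitive")
  expect_gt(st2$beta_bet, 0.9)
})

test_that("weight-change norms are channel-local", {
  net <- init_rnn(tiny_cfg)
  expect_equal(weight_change_norms(net, net)$norm, rep(0, 3))
  net2 <- net
  net2$Wx[3:4, ] <- net2$Wx[3:4, ] + 0.1
  nrm <- weight_change_norms(net, net2)
  expect_gt(nrm$norm[nrm$channel == "opponent"], 0)
  expect_equal(nrm$norm[nrm$channel != "opponent"], rep(0, 2))
  bad <- init_rnn(rnn_config(hidden_units = 3L))
  expect_error(weight_change_norms(net, bad), "shapes differ")
})

test_that("sign reversal is an involution restricted to the named channels", {
  set.seed(64)
  net <- init_rnn(tiny_cfg)
  rev1 <- reverse_input_weights(net)
  expect_equal(rev1$Wx[1:2, ], net$Wx[1:2, ])
  expect_equal(rev1$Wx[3:6, ], -net$Wx[3:6, ])
  expect_equal(reverse_input_weights(rev1)$Wx, net$Wx)
  expect_identical(rev1[c("Wh", "b", "Wy", "by")],
                   net[c("Wh", "b", "Wy", "by")])
})

test_that("step 3 re-optimizes only beta and flags switches", {
  set.seed(65)
  net <- init_rnn(tiny_cfg)
  B <- 30; TT <- 4
  X <- rand_X(B, TT)
  y <- pursuitlab:::lstm_forward(net, X)$pred + 0.5
  cfg2 <- tiny_cfg; cfg2$step2_epoch_cap <- 100L
  st <- rnn_train_step2(net, X, y, cfg2)  # help_sensitive

  unres <- st; unres$classification <- "unresolved"
  expect_error(rnn_reverse_retrain(unres, net, X, y, cfg2), "resolved")

  s3 <- rnn_reverse_retrain(st, net, X, y, cfg2)
  expect_true(s3$classification %in%
                c("betrayal_sensitive", "help_sensitive", "unresolved"))
  expect_equal(s3$switched,
               s3$classification != "unresolved" &&
                 s3$classification != st$classification)
  # with every error still negative after reversal, beta must fall again:
  # predictions changed, so recompute the loss structure instead
  expect_true(is.finite(s3$loss_neg) && is.finite(s3$loss_pos))
})

test_that("holdout adaptation reports train/test accuracy traces", {
  set.seed(66)
  net <- init_rnn(tiny_cfg)
  B <- 40; TT <- 4
  X <- rand_X(B, TT)
  y <- runif(B)
  cfg2 <- tiny_cfg; cfg2$step2_epoch_cap <- 30L
  st <- rnn_holdout_check(net, X, y, cfg2)
  expect_true(all(c("train_accuracy", "test_accuracy") %in%
                    names(st$trace)))
  # smoothed training accuracy trends upward (optimization sanity)
  tr <- st$trace$train_accuracy
  k <- max(3, length(tr) %/% 3)
  expect_gte(mean(tail(tr, k)), mean(head(tr, k)) - 1e-6)
})

test_that("trajectory input encoding has the documented geometry", {
  cfgg <- game_config()
  n <- 200
  traj <- tibble::tibble(
    frame = 0:(n - 1), t = (0:(n - 1)) / 60,
    prey_x = 960, prey_y = 540, oppo_x = 960 + 200, oppo_y = 540,
    play_x = 960, play_y = 540 + 100
  )
  rc <- rnn_config()
  m <- traj_to_input(traj, cfgg, rc)
  expect_equal(dim(m), c(rc$seq_len, 6))
  ppd <- cfgg$px_per_deg
  expect_equal(m[, 1], rep(0, rc$seq_len))  # prey centred
  expect_equal(m[, 3], rep(200 / ppd / rc$coord_scale, rc$seq_len))
  expect_equal(m[, 5], rep(100 / ppd / rc$coord_scale, rc$seq_len))
  d_op <- sqrt(200^2 + 100^2) / ppd / rc$coord_scale
  expect_equal(m[, 4], rep(d_op, rc$seq_len))
})
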