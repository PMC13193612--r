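#' Configuration of the three-step LSTM experiment
#'
#' Architecture and training constants: a sequence input of size 6 (two
#' channels per agent; see [traj_to_input()]), one LSTM layer (64 hidden
#' units) and a scalar linear output predicting the opponent's F. Step 1 trains all
#' weights on inference-phase trajectories (Adam, learning rate 0.01,
#' gradient decay 0.9, summed squared error). Step 2 freezes everything
#' but the input weights and the betrayal-sensitivity mixture weight
#' `beta_bet`, trained on 100 betrayal + 100 help pursuit trials under the
#' asymmetric loss `beta_bet * Loss- + (1 - beta_bet) * Loss+` until
#' `beta_bet` crosses 0.9 or 0.1. Step 3 flips the sign of the opponent
#' and player input columns and re-optimizes only `beta_bet` at learning
#' rate 0.05.
#'
#' Step 1 uses the printed scale of 1000 training trials; the number of
#' step-2 retrainings defaults to a desk scale of 50 (printed scale 1500),
#' reachable through these fields.
#'
#' @param ... overrides of the fields listed in the source.
#' @return A list of class `rnn_config`.
#' @export
rnn_config <- function(...) {
  cfg <- list(
    input_size = 6L,
    hidden_units = 64L,
    seq_len = 30L,          # trajectory resampled to this many timesteps
    input_duration = 3,     # s of trajectory fed to the network; keeping a
                            # common duration and sampling rate across the
                            # inference and pursuit phases avoids a
                            # train/adapt time-scale mismatch
    lr = 0.01,
    adam_beta1 = 0.9,       # "gradient decay"
    adam_beta2 = 0.999,
    adam_eps = 1e-8,
    step1_trials = 1000L,
    step1_epochs = 60L,     # early stop; prolonged fitting memorizes the
                            # inference phases and transfers poorly
    step2_n_per_cond = 100L,
    n_retrainings = 50L,
    step2_epoch_cap = 150L,
    beta_init = 0.5,
    stop_hi = 0.9,
    stop_lo = 0.1,
    lr_step3 = 0.05,
    step3_epoch_cap = 200L,
    coord_scale = 30,       # deg; input coordinates divided by this
    augment_rotations = TRUE  # step-1 only: random per-trial rotation of
                              # the layout each epoch; the intention signal
                              # is rotation-invariant geometry, and the
                              # augmentation stops the network from
                              # memorizing absolute layouts
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown rnn_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$stop_lo < 0.5, cfg$stop_hi > 0.5)
  structure(cfg, class = "rnn_config")
}

# input channel rows of W_ih, in input order (x, y per agent)
rnn_channels <- function() list(prey = 1:2, opponent = 3:4, player = 5:6)

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize an LSTM network
#'
#' Uniform initialization scaled by the hidden size, with the forget-gate
#' bias set to 1. Gate blocks are ordered input, forget, candidate,
#' output.
#'
#' @param cfg an [rnn_config()].
#' @return A list of class `rnn_net` with `Wx` (6 x 4H input weights,
#'   rows = input channels), `Wh` (H x 4H recurrent), `b` (4H), `Wy` (H),
#'   `by` (scalar).
#' @export
init_rnn <- function(cfg = rnn_config()) {
  H <- cfg$hidden_units
  I <- cfg$input_size
  r <- 1 / sqrt(H)
  net <- list(
    Wx = matrix(runif(I * 4 * H, -r, r), I, 4 * H),
    Wh = matrix(runif(H * 4 * H, -r, r), H, 4 * H),
    b = rep(0, 4 * H),
    Wy = runif(H, -r, r),
    by = 0,
    cfg = cfg
  )
  net$b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  structure(net, class = "rnn_net")
}

#' @export
print.rnn_net <- function(x, ...) {
  cat("<rnn_net> LSTM(", x$cfg$hidden_units, ") input ",
      x$cfg$input_size, " -> scalar F-hat\n", sep = "")
  invisible(x)
}

# Forward pass. X: array (B, input, T). Returns predictions and, when
# keep_cache, everything BPTT needs.
lstm_forward <- function(net, X, keep_cache = FALSE) {
  B <- dim(X)[1]; TT <- dim(X)[3]; H <- net$cfg$hidden_units
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  bmat <- matrix(net$b, B, 4 * H, byrow = TRUE)
  cache <- if (keep_cache) vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- X[, , t, drop = FALSE]
    dim(xt) <- c(B, dim(X)[2])
    Z <- xt %*% net$Wx + h %*% net$Wh + bmat
    i <- sigmoid(Z[, gi, drop = FALSE])
    f <- sigmoid(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    o <- sigmoid(Z[, go, drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(x = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, h_prev = h_prev, tc = tc)
    }
  }
  pred <- drop(h %*% net$Wy) + net$by
  list(pred = pred, h_last = h, cache = cache)
}

# Backpropagation through time. dpred: length-B gradient of the loss wrt
# the prediction. Returns gradients for all parameters; with
# wx_only = TRUE the accumulators for the frozen recurrent/output
# parameters are skipped (the error still propagates through them).
lstm_backward <- function(net, fwd, dpred, wx_only = FALSE) {
  H <- net$cfg$hidden_units
  cache <- fwd$cache
  TT <- length(cache)
  B <- length(dpred)
  dWx <- matrix(0, nrow(net$Wx), ncol(net$Wx))
  dWh <- if (!wx_only) matrix(0, H, 4 * H)
  db <- if (!wx_only) rep(0, 4 * H)
  dWy <- if (!wx_only) drop(crossprod(fwd$h_last, dpred))
  dby <- if (!wx_only) sum(dpred)
  dh <- dpred %o% net$Wy
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    k <- cache[[t]]
    do_ <- dh * k$tc
    dc <- dc + dh * k$o * (1 - k$tc^2)
    di <- dc * k$g
    df <- dc * k$c_prev
    dg <- dc * k$i
    dZ <- cbind(di * k$i * (1 - k$i),
                df * k$f * (1 - k$f),
                dg * (1 - k$g^2),
                do_ * k$o * (1 - k$o))
    dWx <- dWx + crossprod(k$x, dZ)
    if (!wx_only) {
      dWh <- dWh + crossprod(k$h_prev, dZ)
      db <- db + colSums(dZ)
    }
    dh <- tcrossprod(dZ, net$Wh)
    dc <- dc * k$f
  }
  list(Wx = dWx, Wh = dWh, b = db, Wy = dWy, by = dby)
}

adam_new <- function() list(t = 0, m = list(), v = list())

adam_step <- function(state, params, grads, lr, b1, b2, eps) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Resample a trajectory into LSTM input
#'
#' Takes the first `input_duration` seconds of a phase trajectory and
#' resamples it to `seq_len` evenly spaced frames. Each agent owns two
#' input channels: the prey's centred screen coordinates (channels 1-2),
#' the opponent's distances to the prey and to the player (3-4), and the
#' player's distances to the prey and to the screen centre (5-6), all in
#' degrees divided by `coord_scale`. The intention signal lives in
#' relative geometry, so per-agent distance channels both transfer across
#' phases and keep each agent's evidence in its own rows of the input
#' weight matrix — which is what makes the input-weight sign-reversal
#' intervention interpretable. Trajectories shorter than `input_duration`
#' are resampled over their full length.
#'
#' @param traj trajectory tibble.
#' @param cfg a [game_config()].
#' @param rnn_cfg an [rnn_config()].
#' @return A `seq_len` x 6 matrix.
#' @export
traj_to_input <- function(traj, cfg = game_config(),
                          rnn_cfg = rnn_config()) {
  n_use <- min(nrow(traj),
               round(rnn_cfg$input_duration * cfg$frame_rate) + 1)
  idx <- round(seq(1, n_use, length.out = rnn_cfg$seq_len))
  m <- as.matrix(traj[idx, c("prey_x", "prey_y", "oppo_x", "oppo_y",
                             "play_x", "play_y")])
  ppd <- cfg$px_per_deg
  cx <- cfg$arena_width / 2
  cy <- cfg$arena_height / 2
  dd <- function(a, b) {
    sqrt((m[, a[1]] - m[, b[1]])^2 + (m[, a[2]] - m[, b[2]])^2) / ppd
  }
  out <- cbind(
    (m[, 1] - cx) / ppd, (m[, 2] - cy) / ppd,   # prey position
    dd(c(3, 4), c(1, 2)), dd(c(3, 4), c(5, 6)), # opponent: to prey, player
    dd(c(5, 6), c(1, 2)),                       # player: to prey
    sqrt((m[, 5] - cx)^2 + (m[, 6] - cy)^2) / ppd # player: to centre
  )
  out / rnn_cfg$coord_scale
}

stack_inputs <- function(mats) {
  TT <- nrow(mats[[1]]); I <- ncol(mats[[1]])
  X <- array(0, c(length(mats), I, TT))
  for (b in seq_along(mats)) X[b, , ] <- t(mats[[b]])
  X
}

#' Step 1: train the F-predictor
#'
#' Full-batch Adam on the summed squared error between the predicted and
#' actual F over the supplied inference-phase trials (gradients
#' accumulated across all trials per update).
#'
#' @param X input array (trials x 6 x timesteps) from [stack_inputs()].
#' @param y true F per trial.
#' @param cfg an [rnn_config()].
#' @param net optional pre-initialized [init_rnn()] network.
#' @return A list: `net` (trained), `trace` (tibble epoch, mse), `mse`
#'   (final training MSE, mean squared error).
#' @export
# Random rotation of the layout about the arena centre. The distance
# channels are rotation-invariant; only the prey coordinate pair moves.
rotate_inputs <- function(X, theta) {
  out <- X
  ct <- cos(theta); st <- sin(theta)
  xs <- X[, 1, ]
  ys <- X[, 2, ]
  out[, 1, ] <- ct * xs - st * ys
  out[, 2, ] <- st * xs + ct * ys
  out
}

rnn_train_step1 <- function(X, y, cfg = rnn_config(), net = NULL) {
  if (is.null(net)) net <- init_rnn(cfg)
  ad <- adam_new()
  trace <- numeric(cfg$step1_epochs)
  pars <- net[c("Wx", "Wh", "b", "Wy", "by")]
  for (ep in seq_len(cfg$step1_epochs)) {
    net[c("Wx", "Wh", "b", "Wy", "by")] <- pars
    Xe <- if (isTRUE(cfg$augment_rotations))
      rotate_inputs(X, runif(dim(X)[1], 0, 2 * pi)) else X
    fwd <- lstm_forward(net, Xe, keep_cache = TRUE)
    err <- fwd$pred - y
    if (any(!is.finite(err))) {
      stop("step-1 training diverged at epoch ", ep,
           " (non-finite loss); lower the learning rate")
    }
    trace[ep] <- mean(err^2)
    grads <- lstm_backward(net, fwd, 2 * err)  # d/dpred sum(err^2)
    st <- adam_step(ad, pars, grads, cfg$lr, cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    ad <- st$state
    pars <- st$params
  }
  net[c("Wx", "Wh", "b", "Wy", "by")] <- pars
  # recentre the output bias: the squared-error optimum has zero mean
  # residual, and a leftover offset cannot be corrected later (biases are
  # frozen in step 2)
  fwd <- lstm_forward(net, X)
  net$by <- net$by - mean(fwd$pred - y)
  fwd <- lstm_forward(net, X)
  list(net = net,
       trace = tibble::tibble(epoch = seq_len(cfg$step1_epochs),
                              mse = trace),
       mse = mean((fwd$pred - y)^2))
}

mixed_loss <- function(err, beta) {
  neg <- err < 0
  pos <- err > 0
  ln <- if (any(neg)) mean(err[neg]^2) else 0
  lp <- if (any(pos)) mean(err[pos]^2) else 0
  list(loss = beta * ln + (1 - beta) * lp, ln = ln, lp = lp,
       neg = neg, pos = pos)
}

#' Step 2: betrayal/help adaptation
#'
#' With the recurrent and output weights frozen, the input weights `W_ih`
#' and the mixture weight `beta_bet` are jointly optimized on the
#' asymmetric loss `beta_bet * Loss- + (1 - beta_bet) * Loss+`, where
#' `Loss-` is the mean squared error over trials with negative prediction
#' error (the betrayal side) and `Loss+` its positive-error counterpart.
#' `beta_bet` starts neutral at 0.5, is clipped to `[0, 1]`, and training
#' stops when it crosses the 0.9 / 0.1 extremes (or at the epoch cap,
#' classified `unresolved`).
#'
#' @param net a step-1 trained [rnn_train_step1()] network.
#' @param X pursuit-trial input array (trials x 6 x timesteps).
#' @param y the F value of the corresponding inference phase (the target
#'   the network was calibrated to).
#' @param cfg an [rnn_config()].
#' @param holdout_idx optional indices of trials excluded from training
#'   and tracked as a test set.
#' @return An object of class `rnn_adapt_state`: `Wx` (adapted input
#'   weights), `beta_bet`, `classification` (`betrayal_sensitive`,
#'   `help_sensitive` or `unresolved`), `epochs`, `trace` (tibble epoch,
#'   beta_bet, loss_neg, loss_pos, loss, plus train/test accuracy when a
#'   holdout is given).
#' @export
rnn_train_step2 <- function(net, X, y, cfg = rnn_config(),
                            holdout_idx = NULL) {
  train_idx <- seq_len(dim(X)[1])
  if (!is.null(holdout_idx)) train_idx <- setdiff(train_idx, holdout_idx)
  Xtr <- X[train_idx, , , drop = FALSE]
  ytr <- y[train_idx]
  ad <- adam_new()
  beta <- cfg$beta_init
  pars <- list(Wx = net$Wx, beta = beta)
  wk <- net
  trace <- vector("list", cfg$step2_epoch_cap)
  classification <- "unresolved"
  ep_done <- 0L
  for (ep in seq_len(cfg$step2_epoch_cap)) {
    wk$Wx <- pars$Wx
    beta <- pars$beta
    fwd <- lstm_forward(wk, Xtr, keep_cache = TRUE)
    err <- fwd$pred - ytr
    ml <- mixed_loss(err, beta)
    dpred <- numeric(length(err))
    if (any(ml$neg)) dpred[ml$neg] <- beta * 2 * err[ml$neg] / sum(ml$neg)
    if (any(ml$pos)) dpred[ml$pos] <- (1 - beta) * 2 * err[ml$pos] /
        sum(ml$pos)
    grads_all <- lstm_backward(wk, fwd, dpred, wx_only = TRUE)
    grads <- list(Wx = grads_all$Wx, beta = ml$ln - ml$lp)
    st <- adam_step(ad, pars, grads, cfg$lr, cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    ad <- st$state
    pars <- st$params
    pars$beta <- min(max(pars$beta, 0), 1)
    row <- tibble::tibble(epoch = ep, beta_bet = pars$beta,
                          loss_neg = ml$ln, loss_pos = ml$lp,
                          loss = ml$loss)
    if (!is.null(holdout_idx)) {
      wk$Wx <- pars$Wx
      acc <- function(idx) {
        fw <- lstm_forward(wk, X[idx, , , drop = FALSE])
        1 - mixed_loss(fw$pred - y[idx], pars$beta)$loss
      }
      row$train_accuracy <- acc(train_idx)
      row$test_accuracy <- acc(holdout_idx)
    }
    trace[[ep]] <- row
    ep_done <- ep
    if (pars$beta > cfg$stop_hi) { classification <- "betrayal_sensitive"; break }
    if (pars$beta < cfg$stop_lo) { classification <- "help_sensitive"; break }
  }
  structure(
    list(Wx = pars$Wx, beta_bet = pars$beta,
         classification = classification, epochs = ep_done,
         trace = dplyr::bind_rows(trace[seq_len(ep_done)])),
    class = "rnn_adapt_state"
  )
}

#' @export
print.rnn_adapt_state <- function(x, ...) {
  cat("<rnn_adapt_state>", x$classification,
      "beta_bet =", format(x$beta_bet, digits = 3),
      "after", x$epochs, "epochs\n")
  invisible(x)
}

net_with_Wx <- function(net, Wx) { net$Wx <- Wx; net }

#' Forward-pass inferential bias of a network
#'
#' Mean of (predicted F - actual F) over a set of inference-phase trials,
#' with no weight updates.
#'
#' @param net an [init_rnn()] network (e.g. a step-2 adapted one).
#' @param X,y inference-trial inputs and true F values.
#' @return A list: `bias` (mean error) and `errors` (per trial).
#' @export
rnn_evaluate_bias <- function(net, X, y) {
  fwd <- lstm_forward(net, X)
  err <- fwd$pred - y
  list(bias = mean(err), errors = err)
}

#' Input-weight change norms per agent channel
#'
#' Euclidean norm of the change in the input weights restricted to each
#' agent's (x, y) input rows, between two networks (or between a network
#' and an adapted state's `Wx`).
#'
#' @param net_before,net_after `rnn_net` objects or raw `Wx` matrices of
#'   identical shape.
#' @return A tibble `channel`, `norm`.
#' @export
weight_change_norms <- function(net_before, net_after) {
  W0 <- if (is.list(net_before)) net_before$Wx else net_before
  W1 <- if (is.list(net_after)) net_after$Wx else net_after
  if (!identical(dim(W0), dim(W1))) stop("input weight shapes differ")
  ch <- rnn_channels()
  tibble::tibble(
    channel = names(ch),
    norm = unname(vapply(ch, function(r) sqrt(sum((W1[r, ] - W0[r, ])^2)),
                         numeric(1)))
  )
}

#' Reverse the opponent and player input weights
#'
#' Flips the sign of the input-weight rows carrying the opponent's and
#' player's positions (an involution: applying it twice restores the
#' original weights).
#'
#' @param net an `rnn_net`.
#' @param channels which agent channels to flip.
#' @return The modified network.
#' @export
reverse_input_weights <- function(net, channels = c("opponent", "player")) {
  ch <- rnn_channels()
  for (nm in channels) net$Wx[ch[[nm]], ] <- -net$Wx[ch[[nm]], ]
  net
}

#' Step 3: sign reversal and beta_bet re-optimization
#'
#' Reverses the opponent and player input weights of a resolved step-2
#' network, freezes every learnable parameter except `beta_bet`, and
#' re-optimizes `beta_bet` from its pre-reversal value under the same
#' mixed loss (learning rate 0.05). Because only `beta_bet` moves, the
#' predictions — and hence `Loss-` and `Loss+` — are fixed, and `beta_bet`
#' walks toward the side with the smaller loss.
#'
#' @param state a resolved `rnn_adapt_state` from [rnn_train_step2()].
#' @param net the step-1 base network the state was adapted from.
#' @param X,y the pursuit trials to evaluate the loss on.
#' @param cfg an [rnn_config()].
#' @return A list: `beta_bet`, `classification`, `switched` (crossed to
#'   the opposite extreme), `trace` (tibble epoch, beta_bet),
#'   `loss_neg`, `loss_pos`.
#' @export
rnn_reverse_retrain <- function(state, net, X, y, cfg = rnn_config()) {
  if (state$classification == "unresolved") {
    stop("step 3 requires a resolved step-2 state")
  }
  wk <- reverse_input_weights(net_with_Wx(net, state$Wx))
  fwd <- lstm_forward(wk, X)
  err <- fwd$pred - y
  ml <- mixed_loss(err, state$beta_bet)
  g <- ml$ln - ml$lp
  beta <- state$beta_bet
  ad <- adam_new()
  pars <- list(beta = beta)
  trace <- tibble::tibble(epoch = integer(0), beta_bet = numeric(0))
  classification <- "unresolved"
  for (ep in seq_len(cfg$step3_epoch_cap)) {
    st <- adam_step(ad, pars, list(beta = g), cfg$lr_step3,
                    cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
    ad <- st$state
    pars <- st$params
    pars$beta <- min(max(pars$beta, 0), 1)
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(epoch = ep,
                                             beta_bet = pars$beta))
    if (pars$beta > cfg$stop_hi) { classification <- "betrayal_sensitive"; break }
    if (pars$beta < cfg$stop_lo) { classification <- "help_sensitive"; break }
  }
  list(beta_bet = pars$beta, classification = classification,
       switched = classification != "unresolved" &&
         classification != state$classification,
       trace = trace, loss_neg = ml$ln, loss_pos = ml$lp)
}

#' Run the full three-step RNN experiment on simulated trials
#'
#' Generates inference-phase trials (uniform F) for step 1, trains the
#' F-predictor, builds betrayal and unexpected-help pursuit pools, runs
#' `n_retrainings` independent step-2 adaptations (fresh 100 + 100 trial
#' draws each), evaluates each adapted network's forward-pass bias on the
#' step-1 trials, and applies the step-3 sign reversal to every resolved
#' network.
#'
#' @param rnn_cfg an [rnn_config()].
#' @param cfg a [game_config()].
#' @param seed integer seed.
#' @param pool_per_cond pursuit trials simulated per condition.
#' @param inference_cap generator cap (s) on inference phases.
#' @param run_step3 logical.
#' @return A list: `step1` (net, trace, mse), `adapt` (tibble with one row
#'   per retraining: classification, final beta_bet, epochs, bias, weight
#'   change norms), `states` (list of `rnn_adapt_state`), `step3` (tibble:
#'   classification before/after, switched), `baseline_bias` (step-1 net
#'   bias on its training set).
#' @export
run_rnn_experiment <- function(rnn_cfg = rnn_config(), cfg = game_config(),
                               seed = NULL, pool_per_cond = 500,
                               inference_cap = 3, run_step3 = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  icfg <- cfg
  icfg$inference_time_cap <- min(inference_cap, cfg$inference_time_cap)

  # ---- step 1 data: inference phases with uniform F
  n1 <- rnn_cfg$step1_trials
  f1 <- runif(n1)
  X1 <- stack_inputs(lapply(seq_len(n1), function(i) {
    traj_to_input(run_inference_phase(f1[i], icfg)$trajectories, cfg,
                  rnn_cfg)
  }))
  step1 <- rnn_train_step1(X1, f1, rnn_cfg)
  baseline_bias <- rnn_evaluate_bias(step1$net, X1, f1)$bias

  # ---- pursuit pools under betrayal / unexpected help; only the first
  # input_duration seconds feed the network, so the simulation stops there
  pcfg <- cfg
  pcfg$pursuit_time_limit <- min(cfg$pursuit_time_limit,
                                 rnn_cfg$input_duration)
  make_pool <- function(sign) {
    f_inf <- runif(pool_per_cond)
    delta <- sign * runif(pool_per_cond, 0.35, 0.45)
    f_pur <- pmin(pmax(f_inf + delta, 0), 1)
    # boost/hinder counterbalanced so opponent speed is not an F cue
    choice <- sample(c("boost", "hinder"), pool_per_cond, replace = TRUE)
    mats <- lapply(seq_len(pool_per_cond), function(i) {
      pur <- run_pursuit_phase(f_pur[i], choice[i], cfg = pcfg,
                               f_inference = f_inf[i])
      traj_to_input(pur$trajectories, cfg, rnn_cfg)
    })
    list(X = stack_inputs(mats), y = f_inf)
  }
  bet <- make_pool(-1)
  hel <- make_pool(+1)

  n2 <- rnn_cfg$step2_n_per_cond
  states <- vector("list", rnn_cfg$n_retrainings)
  rows <- vector("list", rnn_cfg$n_retrainings)
  for (r in seq_len(rnn_cfg$n_retrainings)) {
    ib <- sample(pool_per_cond, n2)
    ih <- sample(pool_per_cond, n2)
    X2 <- abind_first(bet$X[ib, , , drop = FALSE],
                      hel$X[ih, , , drop = FALSE])
    y2 <- c(bet$y[ib], hel$y[ih])
    st <- rnn_train_step2(step1$net, X2, y2, rnn_cfg)
    st$X2 <- NULL
    bias <- rnn_evaluate_bias(net_with_Wx(step1$net, st$Wx), X1, f1)$bias
    nrm <- weight_change_norms(step1$net$Wx, st$Wx)
    s3 <- NULL
    if (run_step3 && st$classification != "unresolved") {
      s3 <- rnn_reverse_retrain(st, step1$net, X2, y2, rnn_cfg)
    }
    states[[r]] <- st
    rows[[r]] <- tibble::tibble(
      retraining = r,
      classification = st$classification,
      beta_final = st$beta_bet,
      epochs = st$epochs,
      bias = bias,
      norm_prey = nrm$norm[nrm$channel == "prey"],
      norm_opponent = nrm$norm[nrm$channel == "opponent"],
      norm_player = nrm$norm[nrm$channel == "player"],
      step3_classification = if (is.null(s3)) NA_character_
                             else s3$classification,
      step3_switched = if (is.null(s3)) NA else s3$switched
    )
  }
  adapt <- dplyr::bind_rows(rows)
  list(step1 = step1, adapt = adapt, states = states,
       baseline_bias = baseline_bias,
       step3 = dplyr::filter(adapt, !is.na(.data$step3_switched)))
}

abind_first <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Overfitting check for step-2 adaptation
#'
#' Runs one step-2 adaptation with half the trials held out and reports
#' per-epoch accuracy (1 - mixed loss) for the training and test halves.
#'
#' @param net a step-1 network.
#' @param X,y pursuit trials (both conditions stacked).
#' @param cfg an [rnn_config()].
#' @param split fraction of trials held out.
#' @return The `rnn_adapt_state`, whose trace carries `train_accuracy`
#'   and `test_accuracy` columns.
#' @export
rnn_holdout_check <- function(net, X, y, cfg = rnn_config(), split = 0.5) {
  B <- dim(X)[1]
  stopifnot(B >= 20)
  holdout <- sample(B, round(B * split))
  rnn_train_step2(net, X, y, cfg, holdout_idx = holdout)
}
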