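feature_names <- function() {
  paste0(rep(c("d_po_", "d_pp_", "d_op_"), each = 5), "t", 1:5)
}

# Rolling per-frame feature matrix. For every frame the trailing 1 s window
# is split into five 200 ms bins (t1 oldest .. t5 newest) and the three
# pairwise distances are averaged within each bin. Early frames use a
# left-truncated window: bins reaching before trial onset take the mean of
# the earliest available frames.
rolling_feature_matrix <- function(dists, frame_rate, window = 1, n_bins = 5) {
  n <- nrow(dists)
  bw <- max(1L, as.integer(round(window * frame_rate / n_bins)))  # frames/bin
  out <- matrix(NA_real_, n, 3 * n_bins)
  for (p in 1:3) {
    d <- dists[, p]
    cs <- cumsum(d)
    # trailing bw-frame mean at every frame (partial at the start)
    lo <- pmax(seq_len(n) - bw, 0L)
    rm_bw <- (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
    for (b in seq_len(n_bins)) {
      lag <- (n_bins - b) * bw
      idx <- pmax(seq_len(n) - lag, 1L)
      out[, (p - 1) * n_bins + b] <- rm_bw[idx]
    }
  }
  colnames(out) <- feature_names()
  out
}

#' Trajectory features for the inference model
#'
#' Computes the 15-dimensional feature vector of an inference-phase
#' trajectory: the three pairwise distances among prey, opponent and player
#' (in degrees), averaged within five 200 ms bins over the 1 s window
#' ending at `window_end`. Ordering is pair-major: prey-opponent,
#' prey-player, opponent-player, each over bins t1 (oldest) to t5 (newest).
#'
#' @param traj a trajectory tibble from [run_inference_phase()] (columns
#'   `prey_x` .. `play_y`).
#' @param cfg a [game_config()].
#' @param window window length in seconds (default 1).
#' @param n_bins number of time bins (default 5).
#' @param window_end frame at which the window ends (default: final frame).
#' @return A named numeric vector of length `3 * n_bins`, with attribute
#'   `truncated` when the trajectory is shorter than the window.
#' @export
build_features <- function(traj, cfg = game_config(), window = 1, n_bins = 5,
                           window_end = nrow(traj)) {
  stopifnot(window_end >= 1, window_end <= nrow(traj))
  mat <- as.matrix(traj[, c("prey_x", "prey_y", "oppo_x", "oppo_y",
                            "play_x", "play_y")])
  dists <- cpp_pair_distances(mat, cfg$px_per_deg)
  feats <- rolling_feature_matrix(dists, cfg$frame_rate, window, n_bins)
  out <- feats[window_end, ]
  attr(out, "truncated") <- window_end < round(window * cfg$frame_rate)
  out
}

#' Fit the autoregressive logistic inference model
#'
#' Maximum-likelihood logistic regression of the boost/hinder choice on the
#' 15 trajectory features and on the previous trial's change in intention
#' (`delta_f_prev`, the hysteresis term):
#' `logit P(boost) = beta0 + beta_t . X + beta_hys * delta_f_prev`.
#' Fits showing signs of perfect separation (non-convergence or runaway
#' coefficients) are refitted with a small ridge penalty and flagged.
#'
#' @param data a data frame holding one row per trial.
#' @param features columns holding the feature matrix; by default the 15
#'   `d_*` columns produced by [build_features()] / [generate_dataset()].
#' @param choice column with the 0/1 (hinder/boost) choice (tidy-eval).
#' @param delta_f_prev column with the previous trial's change in F.
#' @param ridge_lambda penalty used by the stabilized refit.
#' @return An object of class `inference_model` with elements `beta0`,
#'   `beta_t` (named, length 15), `beta_hys`, `loglik`, `loglik_null`,
#'   `converged`, `ridged`, `n`.
#' @export
fit_autoregressive_logit <- function(data, features = feature_names(),
                                     choice = choice_bin,
                                     delta_f_prev = delta_f_prev,
                                     ridge_lambda = 1e-2) {
  y <- dplyr::pull(data, {{ choice }})
  dfp <- dplyr::pull(data, {{ delta_f_prev }})
  X <- as.matrix(data[, features])
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  if (length(y) < 50) {
    warning("fewer than 50 trials; coefficient estimates will be unstable")
  }
  df <- data.frame(y = y, X, dfp = dfp)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  ridged <- FALSE
  if (sep || !fit$converged || any(!is.finite(cf)) || max(abs(cf[-1])) > 50) {
    cf <- ridge_logit(cbind(X, dfp = dfp), y, lambda = ridge_lambda)
    ridged <- TRUE
  }
  ll <- loglik_logit(cf, cbind(X, dfp = dfp), y)
  p0 <- mean(y)
  ll0 <- sum(y * log(max(p0, 1e-12)) + (1 - y) * log(max(1 - p0, 1e-12)))
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  structure(
    list(
      beta0 = unname(cf[1]),
      beta_t = setNames(cf[2:(1 + length(features))], features),
      beta_hys = unname(cf[length(cf)]),
      se = if (ridged) NULL else se,
      loglik = ll,
      loglik_null = ll0,
      converged = ridged || fit$converged,
      ridged = ridged,
      n = length(y)
    ),
    class = "inference_model"
  )
}

loglik_logit <- function(beta, X, y) {
  eta <- drop(cbind(1, X) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Ridge-penalized logistic MLE (intercept unpenalized); used only when the
# plain fit separates.
ridge_logit <- function(X, y, lambda = 1e-2) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1))
  fn <- function(b) {
    eta <- drop(Xi %*% b)
    -(sum(y * eta - log1p(exp(eta)))) + sum(pen * b^2) / 2
  }
  gr <- function(b) {
    eta <- drop(Xi %*% b)
    mu <- plogis(eta)
    -drop(crossprod(Xi, y - mu)) + pen * b
  }
  opt <- stats::optim(rep(0, p), fn, gr, method = "BFGS",
                      control = list(maxit = 500))
  setNames(opt$par, c("(Intercept)", colnames(X)))
}

#' @export
print.inference_model <- function(x, ...) {
  cat("<inference_model> n =", x$n,
      if (x$ridged) "(ridge-stabilized)" else "", "\n")
  cat("  beta0    :", format(x$beta0, digits = 4), "\n")
  cat("  beta_hys :", format(x$beta_hys, digits = 4), "\n")
  cat("  logLik   :", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @rdname fit_autoregressive_logit
#' @param x,object an `inference_model`.
#' @param ... unused.
#' @export
tidy.inference_model <- function(x, ...) {
  est <- c(x$beta0, x$beta_t, x$beta_hys)
  tibble::tibble(
    term = c("beta0", names(x$beta_t), "beta_hys"),
    estimate = unname(est),
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se)
  )
}

#' @rdname fit_autoregressive_logit
#' @export
glance.inference_model <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, logLik_null = x$loglik_null,
    n = x$n, converged = x$converged, ridged = x$ridged
  )
}

#' Inferred intention time series for one trial
#'
#' Applies a fitted [fit_autoregressive_logit()] model frame by frame: at
#' every frame the trailing 1 s feature window feeds the logistic model,
#' producing the moment-by-moment inferred intention F-hat in `[0, 1]`.
#'
#' @param model an `inference_model`.
#' @param traj inference-phase trajectory tibble.
#' @param delta_f_prev the previous trial's change in F (scalar; 0 for the
#'   first trial of a session).
#' @param cfg a [game_config()].
#' @return A tibble with `frame`, `t`, `f_hat`, `truncated` (window
#'   shorter than 1 s).
#' @export
infer_timeseries <- function(model, traj, delta_f_prev = 0,
                             cfg = game_config()) {
  mat <- as.matrix(traj[, c("prey_x", "prey_y", "oppo_x", "oppo_y",
                            "play_x", "play_y")])
  dists <- cpp_pair_distances(mat, cfg$px_per_deg)
  X <- rolling_feature_matrix(dists, cfg$frame_rate)
  eta <- model$beta0 + drop(X %*% model$beta_t) +
    model$beta_hys * delta_f_prev
  tibble::tibble(
    frame = traj$frame,
    t = traj$t,
    f_hat = plogis(eta),
    truncated = seq_len(nrow(traj)) < round(cfg$frame_rate)
  )
}

#' Binned drift of the inferred intention (phase portrait)
#'
#' Pools all frames of a collection of F-hat series, estimates the time
#' derivative by forward difference times the frame rate, and averages it
#' within twenty equal F-hat bins on `[0, 1]`.
#'
#' @param fhat_data a data frame with columns `trial` (series id) and
#'   `f_hat`, frames ordered within trial (e.g. stacked outputs of
#'   [infer_timeseries()]).
#' @param n_bins number of F-hat bins (default 20).
#' @param frame_rate frames per second used for the derivative.
#' @param min_frames bins visited by fewer frames than this report `NA`
#'   drift (single stray frames give unusable derivative estimates).
#' @return A tibble of class `phase_portrait` with one row per bin:
#'   `bin`, `lower`, `upper`, `center`, `g` (mean dF-hat/dt, NA for empty
#'   or under-occupied bins), `n`.
#' @export
phase_portrait <- function(fhat_data, n_bins = 20, frame_rate = 60,
                           min_frames = 10) {
  grp <- dplyr::group_by(fhat_data, .data$trial)
  d <- dplyr::mutate(grp,
                     dfdt = (dplyr::lead(.data$f_hat) - .data$f_hat) *
                       frame_rate)
  d <- dplyr::ungroup(d)
  d <- dplyr::filter(d, !is.na(.data$dfdt))
  if (nrow(d) == 0) stop("no usable frames for the phase portrait")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d$f_hat, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  g <- rep(NA_real_, n_bins)
  n <- integer(n_bins)
  agg <- tapply(d$dfdt, factor(bin, levels = seq_len(n_bins)), mean)
  cnt <- tapply(rep(1L, length(bin)), factor(bin, levels = seq_len(n_bins)),
                sum)
  g[] <- as.numeric(agg)
  n[] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  g[n < min_frames] <- NA_real_
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    center = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    g = g,
    n = n
  )
  class(out) <- c("phase_portrait", class(out))
  out
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Energy landscape from binned drift
#'
#' Integrates the binned drift into a potential over the inferred
#' intention. The default `signed` mode uses `U(x) = -integral of g`, so
#' attractors of the drift are minima of `U`. The `printed_abs` mode
#' integrates `|g|` instead, which is monotone non-decreasing by
#' construction and cannot form interior basins; it is retained for
#' fidelity to the printed formula. Interior missing bins are linearly
#' interpolated before integration, but the landscape is never
#' extrapolated beyond the range of F-hat values actually visited (bins
#' outside it stay `NA`); `U` is also min-max normalized for comparison
#' across participants.
#'
#' @param portrait a [phase_portrait()] tibble (or any tibble with
#'   `center` and `g`).
#' @param mode `"signed"` (default) or `"printed_abs"`.
#' @return A tibble of class `energy_landscape` with `center`, `g`
#'   (interpolated), `U`, `U_norm`, and attributes `mode` and `degenerate`
#'   (flat potential).
#' @export
energy_landscape <- function(portrait, mode = c("signed", "printed_abs")) {
  mode <- match.arg(mode)
  x <- portrait$center
  g <- portrait$g
  occ <- which(!is.na(g))
  if (length(occ) < 3) stop("drift defined on fewer than 3 bins")
  # interpolate interior gaps only; the landscape is not extrapolated
  # beyond the range of inferred-F values actually visited
  lo <- min(occ); hi <- max(occ)
  idx <- lo:hi
  gi <- approx(x[occ], g[occ], xout = x[idx], rule = 2)$y
  g2 <- rep(NA_real_, length(x))
  g2[idx] <- gi
  U <- rep(NA_real_, length(x))
  U[idx] <- if (mode == "signed") -cumtrapz(x[idx], gi)
            else cumtrapz(x[idx], abs(gi))
  rng <- max(U, na.rm = TRUE) - min(U, na.rm = TRUE)
  degenerate <- rng < 1e-12
  U_norm <- if (degenerate) ifelse(is.na(U), NA_real_, 0)
            else (U - min(U, na.rm = TRUE)) / rng
  out <- tibble::tibble(center = x, g = g2, U = U, U_norm = U_norm)
  class(out) <- c("energy_landscape", class(out))
  attr(out, "mode") <- mode
  attr(out, "degenerate") <- degenerate
  out
}

# Fit polynomials of order 1..3 to (center, U), pick by AIC (ties to the
# lower order), and return the fits plus the AIC table.
select_polynomial <- function(x, y, orders = 1:3) {
  fits <- lapply(orders, function(k) lm(y ~ poly(x, k, raw = TRUE)))
  aic <- vapply(fits, AIC, numeric(1))
  best <- which.min(round(aic, 8))  # first (lowest order) wins exact ties
  list(order = orders[best], fit = fits[[best]],
       aic = tibble::tibble(order = orders, aic = aic))
}

poly_eval <- function(cf, x) {
  drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
}

#' Stable fixed point of an energy landscape
#'
#' Fits first- to third-order polynomials to `U(F-hat)`, selects the order
#' with the lowest AIC (Gaussian residual likelihood), and returns the
#' location of the polynomial's minimum over the observed F-hat range. A
#' minimum on the range boundary is allowed and flagged.
#'
#' @param landscape an [energy_landscape()].
#' @return A list with `fixed_point`, `order`, `boundary` (logical),
#'   `coefficients` (of the selected polynomial), `aic` (tibble of order
#'   vs AIC).
#' @export
fixed_point <- function(landscape) {
  ok <- !is.na(landscape$U)
  if (sum(ok) < 4) stop("need at least 4 valid bins to locate a fixed point")
  xs <- landscape$center[ok]
  sel <- select_polynomial(xs, landscape$U[ok])
  cf <- unname(coef(sel$fit))
  # minimum searched over the observed F-hat range
  grid <- seq(min(xs), max(xs), length.out = 1001)
  vals <- poly_eval(cf, grid)
  i <- which.min(vals)
  fp <- grid[i]
  if (i > 1 && i < length(grid)) {
    opt <- optimize(function(z) poly_eval(cf, z),
                    c(grid[i - 1], grid[i + 1]))
    if (opt$objective <= vals[i]) fp <- opt$minimum
  }
  span <- max(xs) - min(xs)
  boundary <- fp <= min(xs) + 1e-3 * span || fp >= max(xs) - 1e-3 * span
  list(fixed_point = fp, order = sel$order, boundary = boundary,
       coefficients = cf, aic = sel$aic, range = c(min(xs), max(xs)))
}

#' Basin depth and steepness
#'
#' Depth is the range of the (pre-normalization) potential. Steepness
#' splits the AIC-selected polynomial at the stable fixed point, fits a
#' straight line to each branch (evaluated at the bin centers), and
#' returns the larger absolute slope. A boundary fixed point yields a
#' one-sided steepness.
#'
#' @param landscape an [energy_landscape()].
#' @param fp optional precomputed [fixed_point()] result.
#' @return A list with `depth`, `steepness`, `slope_left`, `slope_right`,
#'   `fixed_point`, `one_sided`.
#' @export
basin_geometry <- function(landscape, fp = NULL) {
  if (is.null(fp)) fp <- fixed_point(landscape)
  depth <- max(landscape$U, na.rm = TRUE) - min(landscape$U, na.rm = TRUE)
  x <- landscape$center[!is.na(landscape$U)]
  side_slope <- function(xs) {
    if (length(xs) < 2) return(NA_real_)
    unname(coef(lm(poly_eval(fp$coefficients, xs) ~ xs))[2])
  }
  sl <- side_slope(x[x <= fp$fixed_point])
  sr <- side_slope(x[x >= fp$fixed_point])
  list(
    depth = depth,
    steepness = max(abs(c(sl, sr)), na.rm = TRUE),
    slope_left = sl,
    slope_right = sr,
    fixed_point = fp$fixed_point,
    one_sided = is.na(sl) || is.na(sr)
  )
}

#' Per-group energy landscapes
#'
#' Reconstructs landscapes for trial groups (e.g. given-F tercile by
#' betrayal/help history). The group landscape pools the F-hat frames of
#' all participants' trials in the group into one phase portrait and
#' landscape, whose fixed point and basin geometry are reported;
#' participant-level landscapes (where a participant contributes enough
#' trials and bins) are returned in the `per_participant` attribute.
#'
#' @param fhat_data a data frame with one row per frame: `participant`,
#'   `trial`, `f_hat`, plus the grouping columns.
#' @param groups character vector of grouping column names.
#' @param n_bins F-hat bins (default 20).
#' @param frame_rate frames per second.
#' @param min_trials participant-by-group cells with fewer trials are
#'   skipped with a warning.
#' @param mode passed to [energy_landscape()].
#' @return A tibble with one row per group: grouping columns,
#'   `n_participants`, `n_trials`, `fixed_point`, `depth`, `steepness`,
#'   `order`, `boundary`, and a `landscape` list-column (pooled
#'   [energy_landscape()]), plus a `per_participant` attribute tibble of
#'   participant-level fixed points.
#' @export
condition_landscapes <- function(fhat_data, groups, n_bins = 20,
                                 frame_rate = 60, min_trials = 5,
                                 mode = "signed") {
  stopifnot(all(c("participant", "trial", "f_hat") %in% names(fhat_data)),
            all(groups %in% names(fhat_data)))
  skipped <- 0L
  cell_landscape <- function(d) {
    pp <- phase_portrait(d, n_bins = n_bins, frame_rate = frame_rate)
    if (sum(!is.na(pp$g)) < 4) return(NULL)
    ls <- energy_landscape(pp, mode = mode)
    fp <- fixed_point(ls)
    geo <- basin_geometry(ls, fp)
    list(ls = ls, fp = fp, geo = geo)
  }
  per_part <- fhat_data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", groups)))) |>
    dplyr::group_modify(function(d, key) {
      res <- if (dplyr::n_distinct(d$trial) >= min_trials)
        cell_landscape(d) else NULL
      if (is.null(res)) {
        skipped <<- skipped + 1L
        return(tibble::tibble())
      }
      tibble::tibble(fixed_point = res$fp$fixed_point,
                     depth = res$geo$depth,
                     steepness = res$geo$steepness,
                     order = res$fp$order, boundary = res$fp$boundary)
    }) |>
    dplyr::ungroup()
  if (skipped > 0) {
    warning(skipped, " participant-by-group cell(s) were skipped ",
            "(too few trials or occupied bins)")
  }
  pooled <- fhat_data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      res <- cell_landscape(d)
      if (is.null(res)) return(tibble::tibble())
      tibble::tibble(
        n_participants = dplyr::n_distinct(d$participant),
        n_trials = dplyr::n_distinct(paste(d$participant, d$trial)),
        fixed_point = res$fp$fixed_point, depth = res$geo$depth,
        steepness = res$geo$steepness, order = res$fp$order,
        boundary = res$fp$boundary, landscape = list(res$ls)
      )
    }) |>
    dplyr::ungroup()
  attr(pooled, "per_participant") <- per_part
  pooled
}
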