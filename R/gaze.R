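gaze_distances <- function(gaze, traj, ppd) {
  tibble::tibble(
    t = traj$t,
    prey = sqrt((gaze$gaze_x - traj$prey_x)^2 +
                  (gaze$gaze_y - traj$prey_y)^2) / ppd,
    opponent = sqrt((gaze$gaze_x - traj$oppo_x)^2 +
                      (gaze$gaze_y - traj$oppo_y)^2) / ppd,
    player = sqrt((gaze$gaze_x - traj$play_x)^2 +
                    (gaze$gaze_y - traj$play_y)^2) / ppd
  )
}

#' Ternary gaze-allocation weights
#'
#' Inverse mean gaze-to-agent distances within a time window, normalized
#' to sum to 1: how observation was shared among prey, opponent and
#' player. A small floor (0.1 deg) on the mean distances keeps the
#' inverse finite.
#'
#' @param gaze gaze tibble (`t`, `gaze_x`, `gaze_y`), time-aligned with
#'   `traj`.
#' @param traj trajectory tibble of the same phase.
#' @param window numeric length-2, seconds after phase onset (default the
#'   1.5 to 3 s pursuit window); use `NULL` for the whole phase.
#' @param cfg a [game_config()].
#' @param eps distance floor in degrees.
#' @return A tibble `agent`, `weight` (3 rows summing to 1).
#' @export
ternary_weights <- function(gaze, traj, window = c(1.5, 3),
                            cfg = game_config(), eps = 0.1) {
  stopifnot(nrow(gaze) == nrow(traj))
  d <- gaze_distances(gaze, traj, cfg$px_per_deg)
  if (!is.null(window)) {
    keep <- d$t >= window[1] & d$t <= window[2]
    if (!any(keep)) stop("window lies outside the trial")
    d <- d[keep, ]
  }
  inv <- 1 / (pmax(colMeans(d[, c("prey", "opponent", "player")]), eps))
  tibble::tibble(agent = c("prey", "opponent", "player"),
                 weight = as.numeric(inv / sum(inv)))
}

#' Opponent-vs-player gaze comparison
#'
#' Per-frame difference between the gaze distance to the opponent and to
#' the player's avatar (degrees); negative values mean the gaze was closer
#' to the opponent. Also returns the mean over the analysis window.
#'
#' @inheritParams ternary_weights
#' @return A list with `series` (tibble `frame`, `t`, `comparison`) and
#'   `window_mean`.
#' @export
gaze_comparison <- function(gaze, traj, window = c(1.5, 3),
                            cfg = game_config()) {
  stopifnot(nrow(gaze) == nrow(traj))
  d <- gaze_distances(gaze, traj, cfg$px_per_deg)
  series <- tibble::tibble(frame = traj$frame, t = traj$t,
                           comparison = d$opponent - d$player)
  keep <- series$t >= window[1] & series$t <= window[2]
  list(series = series,
       window_mean = if (any(keep)) mean(series$comparison[keep])
                     else NA_real_)
}

#' Jerk strength of a movement path
#'
#' Mean squared third time-derivative of the path, the control-stability
#' measure: third-order finite differences per axis, scaled by the cube of
#' the frame rate, squared, summed over axes and averaged over frames.
#' Units deg^2/s^6 when `px_per_deg` is supplied.
#'
#' @param path n x 2 matrix (or tibble) of positions, px.
#' @param frame_rate frames per second.
#' @param px_per_deg pixels per degree (1 keeps pixel units).
#' @return Mean squared jerk.
#' @export
jerk_strength <- function(path, frame_rate = 60, px_per_deg = 35) {
  path <- as.matrix(path)
  if (nrow(path) < 4) stop("need at least 4 frames to estimate jerk")
  j <- diff(path / px_per_deg, differences = 3) * frame_rate^3
  mean(rowSums(j^2))
}

#' Partial Spearman correlation
#'
#' Spearman correlation between `x` and `y` after removing the linear
#' effect of the (ranked) control variables from both rank vectors. With
#' no controls this is the plain Spearman rho.
#'
#' @param x,y numeric vectors.
#' @param controls optional data frame / matrix of control variables.
#' @return The partial rank correlation; `NA` (with a warning) when an
#'   input is constant.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (is.null(controls) || NCOL(controls) == 0) return(cor(rx, ry))
  rc <- apply(as.matrix(controls), 2, rank)
  cor(resid(lm(rx ~ rc)), resid(lm(ry ~ rc)))
}

#' Cluster-based permutation test for paired time series
#'
#' Per-timepoint paired t-tests between two conditions; neighbouring
#' supra-threshold timepoints of the same sign form clusters whose mass is
#' the summed t-value. The null distribution of the maximum absolute
#' cluster mass is built by randomly flipping each participant's
#' difference sign; cluster p-values are the permutation fractions with
#' `(1 + k) / (1 + n_perm)` smoothing.
#'
#' @param series_a,series_b participants x timepoints matrices, paired by
#'   row.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha_cluster two-tailed cluster-forming alpha on the paired t
#'   (default 0.05).
#' @return A list with `clusters` (tibble `start`, `end`, `sign`, `mass`,
#'   `p_value`), `t_series`, `threshold`, `n_perm`.
#' @export
cluster_permutation_test <- function(series_a, series_b, n_perm = 1000,
                                     alpha_cluster = 0.05) {
  A <- as.matrix(series_a)
  B <- as.matrix(series_b)
  stopifnot(identical(dim(A), dim(B)), nrow(A) >= 3)
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  D <- A - B
  n <- nrow(D)
  thr <- qt(1 - alpha_cluster / 2, n - 1)
  tser <- col_t(D, n)
  obs <- find_clusters(tser, thr)

  ss <- colSums(D^2)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- S %*% D / n
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  Tm <- M / sqrt(V / n)
  null_max <- vapply(seq_len(n_perm), function(i) {
    cl <- find_clusters(Tm[i, ], thr)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  }, numeric(1))

  obs$p_value <- vapply(obs$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (1 + n_perm)
  }, numeric(1))
  list(clusters = obs, t_series = tser, threshold = thr, n_perm = n_perm)
}

col_t <- function(D, n) {
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  m / (s / sqrt(n))
}

find_clusters <- function(tser, thr) {
  above <- abs(tser) > thr & !is.na(tser)
  sgn <- sign(tser)
  runs <- rle(above & TRUE)
  out <- list()
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i]) {
      idx <- pos:(pos + len - 1L)
      # split runs where the sign flips within a supra-threshold stretch
      sp <- split(idx, cumsum(c(1, diff(sgn[idx]) != 0)))
      for (g in sp) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = min(g), end = max(g), sign = sgn[g[1]],
          mass = sum(tser[g]))
      }
    }
    pos <- pos + len
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(start = integer(0), end = integer(0),
                      sign = numeric(0), mass = numeric(0))
}

#' Correlation between opponent-directed gaze and next-trial bias
#'
#' Spearman correlation (and linear slope) between a per-trial
#' opponent-gaze measure — the negative of the window-averaged
#' opponent-minus-player gaze comparison, so larger = more opponent
#' observation — and the next trial's inferential bias (choice - given F).
#'
#' @param data a data frame with one row per trial.
#' @param gaze_measure column with the opponent-gaze measure (tidy-eval).
#' @param bias column with the next-trial bias.
#' @return A one-row tibble: `rho`, `p_value`, `slope`, `n`.
#' @export
gaze_bias_correlation <- function(data, gaze_measure = opp_gaze,
                                  bias = next_bias) {
  g <- dplyr::pull(data, {{ gaze_measure }})
  b <- dplyr::pull(data, {{ bias }})
  keep <- complete.cases(g, b)
  g <- g[keep]; b <- b[keep]
  if (length(g) < 5) stop("need at least 5 paired observations")
  ct <- suppressWarnings(stats::cor.test(g, b, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(coef(lm(b ~ g))[2]), n = length(g))
}
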