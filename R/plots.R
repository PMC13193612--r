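#' Plot an energy landscape
#'
#' Normalized potential over the inferred intention, with the stable
#' fixed point marked.
#'
#' @param object an [energy_landscape()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.energy_landscape <- function(object, ...) {
  fp <- tryCatch(fixed_point(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$center,
                                            y = .data$U_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "inferred intention (F-hat)",
                  y = "normalized potential U",
                  title = paste0("Energy landscape (",
                                 attr(object, "mode"), " mode)")) +
    ggplot2::theme_minimal()
  if (!is.null(fp)) {
    p <- p + ggplot2::geom_vline(xintercept = fp$fixed_point,
                                 linetype = "dashed")
  }
  p
}

#' Plot a phase portrait
#'
#' Binned mean drift of the inferred intention; zero crossings with
#' negative slope are attractors.
#'
#' @param object a [phase_portrait()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.phase_portrait <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$g)),
                  ggplot2::aes(x = .data$center, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), show.legend = FALSE) +
    ggplot2::labs(x = "inferred intention (F-hat)",
                  y = "mean dF-hat/dt (1/s)") +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Binned boost proportions with the fitted cumulative Gaussian.
#'
#' @param object a [fit_psychometric()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(0, 1, length.out = 200))
  p <- ggplot2::ggplot(dplyr::filter(object$bins, .data$n > 0),
                       ggplot2::aes(x = .data$center, y = .data$p_boost)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "given F", y = "P(boost)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    grid$y <- stats::pnorm((grid$x - object$mu) / object$sigma)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$x, y = .data$y))
  }
  p
}

#' Plot agent trajectories of one trial
#'
#' @param traj a trajectory tibble.
#' @return A ggplot with one path per agent.
#' @export
plot_trial <- function(traj) {
  long <- dplyr::bind_rows(
    tibble::tibble(agent = "prey", t = traj$t, x = traj$prey_x,
                   y = traj$prey_y),
    tibble::tibble(agent = "opponent", t = traj$t, x = traj$oppo_x,
                   y = traj$oppo_y),
    tibble::tibble(agent = "player", t = traj$t, x = traj$play_x,
                   y = traj$play_y)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$agent)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot beta_bet adaptation traces
#'
#' One line per retraining, with the 0.9 / 0.1 resolution thresholds.
#'
#' @param states list of `rnn_adapt_state` (e.g.
#'   `run_rnn_experiment()$states`).
#' @param cfg an [rnn_config()] (for the thresholds).
#' @return A ggplot.
#' @export
plot_beta_traces <- function(states, cfg = rnn_config()) {
  tr <- purrr::imap_dfr(states, function(s, i) {
    d <- s$trace[, c("epoch", "beta_bet")]
    d$retraining <- i
    d
  })
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$beta_bet,
                                   group = .data$retraining)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(cfg$stop_lo, cfg$stop_hi),
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "beta_bet") +
    ggplot2::theme_minimal()
}
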