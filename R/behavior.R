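#' Fit a cumulative-Gaussian psychometric curve
#'
#' Bins the given F values into equal intervals, computes the boost
#' proportion per bin, and least-squares fits a Gaussian CDF
#' `pnorm((F - mu) / sigma)` to the binned proportions. `mu` is the point
#' of subjective equality and `sigma` the spread.
#'
#' @param data a data frame with one row per trial.
#' @param choice column with the 0/1 (hinder/boost) choice (tidy-eval).
#' @param f column with the given F values.
#' @param n_bins number of equal F bins (default 10).
#' @return An object of class `psychometric_fit`: `mu`, `sigma`, `bins`
#'   (tibble of centers, proportions, counts), `sse`, `degenerate`
#'   (all-boost or all-hinder data), `n`.
#' @export
fit_psychometric <- function(data, choice = choice_bin, f = f_inference,
                             n_bins = 10) {
  y <- dplyr::pull(data, {{ choice }})
  x <- dplyr::pull(data, {{ f }})
  stopifnot(length(y) == length(x), all(y %in% 0:1))
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  centers <- (edges[-(n_bins + 1)] + edges[-1]) / 2
  prop <- tapply(y, factor(bin, levels = seq_len(n_bins)), mean)
  cnt <- tapply(y, factor(bin, levels = seq_len(n_bins)), length)
  bins <- tibble::tibble(center = centers, p_boost = as.numeric(prop),
                         n = ifelse(is.na(cnt), 0L, as.integer(cnt)))
  used <- bins[bins$n > 0, ]
  if (nrow(used) < 2) stop("need data in at least 2 bins")
  degenerate <- all(y == y[1])
  if (degenerate) {
    fit <- structure(
      list(mu = NA_real_, sigma = NA_real_, bins = bins, sse = NA_real_,
           degenerate = TRUE, n = length(y)),
      class = "psychometric_fit")
    return(fit)
  }
  sse <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    sum((used$p_boost - stats::pnorm((used$center - mu) / sigma))^2)
  }
  init <- c(stats::weighted.mean(used$center, used$n * used$p_boost *
                                   (1 - used$p_boost) + 1e-3), log(0.2))
  opt <- stats::optim(init, sse, method = "L-BFGS-B",
                      lower = c(-Inf, log(1e-3)), upper = c(Inf, log(10)))
  structure(
    list(mu = opt$par[1], sigma = exp(opt$par[2]), bins = bins,
         sse = opt$value, degenerate = FALSE, n = length(y)),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> n =", x$n, "\n")
  if (x$degenerate) cat("  degenerate (single response category)\n")
  else cat("  mu =", format(x$mu, digits = 4),
           " sigma =", format(x$sigma, digits = 4),
           " JND =", format(jnd(x), digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x,object a `psychometric_fit`.
#' @param ... unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma,
                 jnd = if (x$degenerate) NA_real_ else jnd(x),
                 sse = x$sse, n = x$n, degenerate = x$degenerate)
}

#' Just-noticeable difference of a psychometric fit
#'
#' Half the distance between the 25% and 75% points of the fitted Gaussian
#' CDF, i.e. `qnorm(0.75) * sigma` (~ 0.6745 sigma). Invariant to `mu`.
#'
#' @param fit a [fit_psychometric()] result.
#' @return The JND on the F axis.
#' @export
jnd <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (fit$degenerate) stop("degenerate psychometric fit has no JND")
  qnorm(0.75) * fit$sigma
}

#' Inferential bias
#'
#' Mean of (choice - given F) with boost coded 1. Negative values mean the
#' opponent's intention was rated more competitive than it actually was.
#'
#' @inheritParams fit_psychometric
#' @return A single number.
#' @export
inferential_bias <- function(data, choice = choice_bin, f = f_inference) {
  y <- dplyr::pull(data, {{ choice }})
  x <- dplyr::pull(data, {{ f }})
  if (length(y) == 0) stop("no trials")
  stopifnot(all(y %in% 0:1))
  mean(y - x)
}

#' Shannon entropy of the boost choice
#'
#' Binary entropy `-p log2 p - (1-p) log2 (1-p)` of the boost probability,
#' maximal (1 bit) at p = 0.5 and zero at certainty, with `0 log 0 = 0`.
#' `one_term = TRUE` evaluates only the `-p log2 p` term instead (maximum
#' ~0.531 bits at p = 1/e).
#'
#' @param p boost probability in `[0, 1]` (vectorized).
#' @param one_term use the single-term variant.
#' @return Entropy in bits.
#' @export
#' @examples
#' choice_entropy(0.5)   # 1 bit
#' choice_entropy(c(0, 1))
choice_entropy <- function(p, one_term = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  xlogx <- function(q) ifelse(q > 0, q * log2(q), 0)
  if (one_term) -xlogx(p) else -xlogx(p) - xlogx(1 - p)
}

#' Choice entropy per given-F bin and condition
#'
#' Boost proportions per equal F bin, converted to entropy, separately per
#' condition. Empty bins propagate as `NA`.
#'
#' @inheritParams fit_psychometric
#' @param condition column with the condition labels.
#' @param one_term passed to [choice_entropy()].
#' @return A tibble: `condition`, `bin`, `center`, `n`, `p_boost`,
#'   `entropy`.
#' @export
entropy_by_F <- function(data, choice = choice_bin, f = f_inference,
                         condition = condition, n_bins = 10,
                         one_term = FALSE) {
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ choice }}),
    x = dplyr::pull(data, {{ f }}),
    cond = dplyr::pull(data, {{ condition }})
  )
  edges <- seq(0, 1, length.out = n_bins + 1)
  centers <- (edges[-(n_bins + 1)] + edges[-1]) / 2
  df$bin <- pmin(pmax(findInterval(df$x, edges, rightmost.closed = TRUE),
                      1L), n_bins)
  grid <- tidyr::expand_grid(cond = unique(df$cond),
                             bin = seq_len(n_bins))
  out <- df |>
    dplyr::group_by(.data$cond, .data$bin) |>
    dplyr::summarise(n = dplyr::n(), p_boost = mean(.data$y),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("cond", "bin")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      center = centers[.data$bin],
      entropy = ifelse(.data$n > 0, choice_entropy(
        ifelse(is.na(.data$p_boost), 0, .data$p_boost),
        one_term = one_term), NA_real_),
      entropy = ifelse(.data$n > 0, .data$entropy, NA_real_)
    ) |>
    dplyr::rename(condition = "cond") |>
    dplyr::arrange(.data$condition, .data$bin) |>
    dplyr::select("condition", "bin", "center", "n", "p_boost", "entropy")
  out
}

#' Signal-detection metrics of the boost choice
#'
#' Treats high-F trials (`F > signal_threshold`) as signal and the rest as
#' noise; a boost response is a hit on signal trials and a false alarm on
#' noise trials. Returns `d' = Z(hit) - Z(fa)` and criterion
#' `c = -(Z(hit) + Z(fa)) / 2`, where Z is the inverse normal CDF. Rates of
#' exactly 0 or 1 are log-linearly corrected (`(k + 0.5) / (n + 1)`) so Z
#' stays finite.
#'
#' @inheritParams fit_psychometric
#' @param signal_threshold F above which a trial counts as signal
#'   (default 0.5).
#' @param correction `"loglinear"` (applied to degenerate rates) or
#'   `"none"`.
#' @return A one-row tibble: `hit_rate`, `fa_rate`, `d_prime`, `criterion`,
#'   `n_signal`, `n_noise`.
#' @export
sdt_metrics <- function(data, choice = choice_bin, f = f_inference,
                        signal_threshold = 0.5,
                        correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  y <- dplyr::pull(data, {{ choice }})
  x <- dplyr::pull(data, {{ f }})
  sig <- x > signal_threshold
  if (!any(sig) || !any(!sig)) stop("need both signal and noise trials")
  rate <- function(k, n) {
    r <- k / n
    if (correction == "loglinear" && (r == 0 || r == 1)) {
      r <- (k + 0.5) / (n + 1)
    }
    r
  }
  hit <- rate(sum(y[sig]), sum(sig))
  fa <- rate(sum(y[!sig]), sum(!sig))
  sdt_from_rates(hit, fa) |>
    dplyr::mutate(n_signal = sum(sig), n_noise = sum(!sig))
}

#' @rdname sdt_metrics
#' @param hit_rate,fa_rate raw hit and false-alarm proportions in (0, 1).
#' @export
sdt_from_rates <- function(hit_rate, fa_rate) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  zh <- qnorm(hit_rate)
  zf <- qnorm(fa_rate)
  tibble::tibble(hit_rate = hit_rate, fa_rate = fa_rate,
                 d_prime = zh - zf, criterion = -(zh + zf) / 2)
}

#' Sensitivity of the next choice to the previous reward
#'
#' Normalizes previous-trial rewards to `[0, 1]`, bins them into equal
#' intervals, and regresses the binned boost probability on the bin
#' centers; also reports a median-split comparison (slope of the low- vs
#' high-reward halves).
#'
#' @param data a data frame with one row per trial.
#' @param prev_reward column with the previous trial's reward (tidy-eval).
#' @param next_choice column with the current 0/1 choice.
#' @param n_bins number of reward bins (default 20).
#' @return A one-row tibble: `slope`, `intercept`, `slope_low`,
#'   `slope_high`, `n_bins_used`, `flagged` (constant rewards).
#' @export
reward_sensitivity <- function(data, prev_reward = prev_reward,
                               next_choice = choice_bin, n_bins = 20) {
  r <- dplyr::pull(data, {{ prev_reward }})
  y <- dplyr::pull(data, {{ next_choice }})
  keep <- !is.na(r) & !is.na(y)
  r <- r[keep]; y <- y[keep]
  if (length(r) == 0) stop("no trials")
  if (max(r) == min(r)) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          slope_low = NA_real_, slope_high = NA_real_,
                          n_bins_used = 0L, flagged = TRUE))
  }
  rn <- (r - min(r)) / (max(r) - min(r))
  binned <- binned_choice(rn, y, n_bins)
  if (nrow(binned) < 2) stop("need at least 2 non-empty reward bins")
  fit <- lm(p ~ center, data = binned)
  med <- median(rn)
  lo <- binned_choice(rn[rn <= med], y[rn <= med], n_bins)
  hi <- binned_choice(rn[rn > med], y[rn > med], n_bins)
  slope_of <- function(b) {
    if (nrow(b) < 2) NA_real_ else unname(coef(lm(p ~ center, data = b))[2])
  }
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_low = slope_of(lo),
    slope_high = slope_of(hi),
    n_bins_used = nrow(binned),
    flagged = FALSE
  )
}

binned_choice <- function(x, y, n_bins) {
  if (length(x) == 0) return(tibble::tibble(center = numeric(0),
                                            p = numeric(0)))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  centers <- (edges[-(n_bins + 1)] + edges[-1]) / 2
  p <- tapply(y, factor(bin, levels = seq_len(n_bins)), mean)
  out <- tibble::tibble(center = centers, p = as.numeric(p))
  out[!is.na(out$p), ]
}
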