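test_that("psychometric fit recovers a known cumulative Gaussian", {
  set.seed(30)
  f <- runif(5000)
  d <- tibble::tibble(
    f_inference = f,
    choice_bin = rbinom(5000, 1, pnorm((f - 0.5) / 0.15))
  )
  fit <- fit_psychometric(d)
  expect_lt(abs(fit$mu - 0.5), 0.02)
  expect_lt(abs(fit$sigma - 0.15), 0.03)
  expect_equal(jnd(fit), qnorm(0.75) * fit$sigma)

  # translation equivariance
  d2 <- dplyr::mutate(d, f_inference = f_inference + 0.1)
  fit2 <- fit_psychometric(d2)
  expect_lt(abs(fit2$mu - (fit$mu + 0.1)), 0.02)

  # step-function limit
  d3 <- tibble::tibble(f_inference = f,
                       choice_bin = as.integer(f > 0.5))
  fit3 <- fit_psychometric(d3)
  expect_lt(abs(fit3$mu - 0.5), 0.06)
  expect_lt(fit3$sigma, 0.02)

  # degenerate single-category data is flagged
  d4 <- tibble::tibble(f_inference = f, choice_bin = 1L)
  fit4 <- fit_psychometric(d4)
  expect_true(fit4$degenerate)
  expect_error(jnd(fit4), "degenerate")

  # broom-style accessors
  expect_named(tidy(fit), c("term", "estimate"))
  expect_true(all(c("mu", "sigma", "jnd") %in% names(glance(fit))))
})

test_that("inferential bias is the mean choice-minus-F", {
  d <- tibble::tibble(f_inference = c(1, 1), choice_bin = c(1L, 1L))
  expect_equal(inferential_bias(d), 0)
  d2 <- tibble::tibble(f_inference = c(0.5, 0.5), choice_bin = c(0L, 0L))
  expect_equal(inferential_bias(d2), -0.5)
  expect_error(inferential_bias(d2[0, ]), "no trials")
})

test_that("binary entropy: maximum, endpoints, closed form, concavity", {
  expect_equal(choice_entropy(0.5), 1)
  expect_equal(choice_entropy(c(0, 1)), c(0, 0))
  expect_equal(choice_entropy(0.25), 0.811278, tolerance = 1e-6)
  expect_error(choice_entropy(1.2), "0, 1")
  p <- seq(0.001, 0.999, length.out = 999)
  h <- choice_entropy(p)
  expect_equal(p[which.max(h)], 0.5, tolerance = 2e-3)
  expect_true(all(diff(h, differences = 2) < 1e-8))  # concave
  # printed one-term variant peaks at 1/e with value log2(e)/e
  h1 <- choice_entropy(p, one_term = TRUE)
  expect_equal(p[which.max(h1)], 1 / exp(1), tolerance = 2e-3)
  expect_equal(max(h1), log2(exp(1)) / exp(1), tolerance = 1e-4)
})

test_that("entropy-by-F curves: identity across equal conditions, bounds", {
  set.seed(31)
  d <- tibble::tibble(
    f_inference = rep(runif(400), 2),
    choice_bin = rep(rbinom(400, 1, 0.5), 2),
    condition = rep(c("a", "b"), each = 400)
  )
  out <- entropy_by_F(d)
  wide <- tidyr::pivot_wider(out[, c("condition", "bin", "entropy")],
                             names_from = "condition",
                             values_from = "entropy")
  expect_equal(wide$a, wide$b)
  expect_true(all(out$entropy >= 0 & out$entropy <= 1, na.rm = TRUE))
  # empty bins propagate as NA
  d2 <- dplyr::filter(d, f_inference < 0.8)
  out2 <- entropy_by_F(d2)
  expect_true(any(is.na(out2$entropy)))
  expect_equal(nrow(out2), 20)  # full grid retained
})

test_that("SDT closed forms and the extreme-rate correction", {
  r <- sdt_from_rates(0.8, 0.2)
  expect_equal(r$d_prime, qnorm(0.8) - qnorm(0.2))
  expect_equal(r$d_prime, 1.683, tolerance = 1e-3)
  expect_equal(r$criterion, 0)
  expect_equal(sdt_from_rates(0.3, 0.3)$d_prime, 0)

  set.seed(32)
  d <- tibble::tibble(f_inference = runif(200),
                      choice_bin = rbinom(200, 1, 0.5))
  out <- sdt_metrics(d)
  expect_true(all(c("d_prime", "criterion") %in% names(out)))
  # all-boost data stays finite through the log-linear correction
  d2 <- tibble::tibble(f_inference = runif(50), choice_bin = 1L)
  out2 <- sdt_metrics(d2)
  expect_true(is.finite(out2$d_prime))
  expect_error(sdt_metrics(dplyr::filter(d, f_inference > 0.6)),
               "signal and noise")
})

test_that("JND is scale-only: proportional to sigma, invariant to mu", {
  f1 <- structure(list(mu = 0.3, sigma = 0.2, degenerate = FALSE),
                  class = "psychometric_fit")
  f2 <- structure(list(mu = 0.7, sigma = 0.2, degenerate = FALSE),
                  class = "psychometric_fit")
  expect_equal(jnd(f1), 0.1349, tolerance = 1e-4)
  expect_equal(jnd(f1), jnd(f2))
  f3 <- structure(list(mu = 0.5, sigma = 1e-6, degenerate = FALSE),
                  class = "psychometric_fit")
  expect_lt(jnd(f3), 1e-5)
})

test_that("reward sensitivity: null, constructed dependence, lm oracle", {
  set.seed(33)
  n <- 2000
  d <- tibble::tibble(prev_reward = runif(n, 0, 100),
                      choice_bin = rbinom(n, 1, 0.5))
  out <- rewards <- reward_sensitivity(d)
  # null slope within 2 SE of zero (SE from an lm refit on the bins)
  rn <- (d$prev_reward - min(d$prev_reward)) /
    (max(d$prev_reward) - min(d$prev_reward))
  b <- pursuitlab:::binned_choice(rn, d$choice_bin, 20)
  se <- summary(lm(p ~ center, data = b))$coefficients[2, 2]
  expect_lt(abs(out$slope), 2.5 * se)
  # oracle equality of the slope on the binned table
  expect_equal(out$slope, unname(coef(lm(p ~ center, data = b))[2]))

  d2 <- dplyr::mutate(d, choice_bin = as.integer(prev_reward >
                                                   median(prev_reward)))
  expect_gt(reward_sensitivity(d2)$slope, 0.5)

  d3 <- dplyr::mutate(d, prev_reward = 7)
  expect_true(reward_sensitivity(d3)$flagged)
})

test_that("bias is antisymmetric under relabeling choices and F", {
  ds <- small_dataset()
  tr <- ds$trials
  b1 <- inferential_bias(tr)
  flipped <- dplyr::mutate(tr, choice_bin = 1L - choice_bin,
                           f_inference = 1 - f_inference)
  expect_equal(inferential_bias(flipped), -b1)
})

test_that("synthetic betrayal history produces the competitive-bias split", {
  tr <- with_prev_condition(small_dataset()$trials)
  bias <- tr |>
    dplyr::filter(!is.na(prev_condition)) |>
    dplyr::group_by(prev_condition) |>
    dplyr::summarise(b = mean(choice_bin - f_inference), .groups = "drop")
  b_bet <- bias$b[bias$prev_condition == "betrayal"]
  b_help <- bias$b[bias$prev_condition == "unexpected_help"]
  expect_lt(b_bet, 0)
  expect_lt(b_bet, b_help)
})
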