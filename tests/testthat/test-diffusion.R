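test_that("noise schedules follow the closed-form cumulative product", {
  s <- make_schedule(T = 2, beta_min = 0.5, beta_max = 0.5, t_star = 1)
  expect_equal(s$alpha_bars, c(0.5, 0.25))

  # frozen values from an independent step-by-step product over 50 factors
  sdef <- make_schedule()  # T = 50, betas 1e-4 .. 0.02
  expect_equal(sdef$alpha_bars[50], 0.60295159733, tolerance = 1e-10)
  shot <- make_schedule(T = 50, beta_min = 1e-4, beta_max = 0.2, t_star = 25)
  expect_equal(shot$alpha_bars[50], 0.00461611101127, tolerance = 1e-9)

  for (args in list(list(T = 5), list(T = 31), list(T = 2))) {
    sc <- do.call(make_schedule, c(args, list(t_star = 1)))
    expect_true(all(diff(sc$alpha_bars) < 0))
    expect_true(sc$alpha_bars[sc$T] > 0 && sc$alpha_bars[1] < 1)
  }

  expect_error(make_schedule(T = 1), "T must")
  expect_error(make_schedule(beta_min = 0), "beta_min")
  expect_error(make_schedule(beta_min = 0.3, beta_max = 0.2), "beta_min")
  expect_error(make_schedule(T = 10, t_star = 11), "t_star")
})

test_that("forward noising matches its closed-form marginal", {
  s <- make_schedule(T = 4, beta_min = 0.5, beta_max = 0.75, t_star = 2)
  # alpha_bar_2 = 0.5 * (1 - 7/12) -> pick t with a handy value instead:
  # use a schedule where alpha_bar_t = 0.25 exactly
  s2 <- make_schedule(T = 2, beta_min = 0.5, beta_max = 0.5, t_star = 2)

  # t = 0 is the identity
  m <- matrix(c(2, -1, 0.5, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  h0 <- forward_noise(m, s2, 0)
  expect_identical(h0$H, m)

  # Monte-Carlo vs closed form: input 2.0 at alpha_bar = 0.25 has mean
  # sqrt(0.25)*2 = 1 and variance 0.75
  n_draws <- 2e5
  big <- matrix(2, nrow = n_draws, ncol = 1, dimnames = list(NULL, "v"))
  h <- forward_noise(big, s2, 2, rng_seed = 99)
  se_mean <- sqrt(0.75 / n_draws)
  expect_lt(abs(mean(h$H) - 1), 3 * se_mean)
  expect_lt(abs(var(as.numeric(h$H)) - 0.75), 3 * 0.75 * sqrt(2 / n_draws))

  expect_error(forward_noise(m, s2, 3), "t must")
})

test_that("training reduces the noise-prediction loss and is seed-stable", {
  m <- tiny_matrix(n = 200, seed = 21)
  s <- make_schedule(T = 20, t_star = 10)
  fit <- train_denoiser(m, s, epochs = 80, seed = 5)
  expect_length(fit$training_log, 80)
  expect_lt(fit$training_log[80], fit$training_log[1])

  fit2 <- train_denoiser(m, s, epochs = 80, seed = 5)
  expect_identical(fit$training_log, fit2$training_log)
  expect_identical(fit$params, fit2$params)

  expect_error(train_denoiser(m, s, epochs = 0), "epochs")
  expect_error(train_denoiser(m[1, , drop = FALSE], s), "2 training samples")
})

test_that("generation is exact at t_star = 0 and deterministic on demand", {
  m <- tiny_matrix(n = 40, seed = 2)
  s <- make_schedule(T = 20, t_star = 10)
  fit <- train_denoiser(m, s, epochs = 30, seed = 1)

  h0 <- forward_noise(m, s, 0)
  expect_identical(generate_outcome(fit, h0, s, 3L), m[, 3])

  h <- forward_noise(m, s, 10, rng_seed = 4)
  g1 <- generate_outcome(fit, h, s, 3L, deterministic = TRUE)
  g2 <- generate_outcome(fit, h, s, 3L, deterministic = TRUE)
  expect_identical(g1, g2)

  bad <- structure(list(H = m[, 1:2], t = 10L), class = "cdd_hidden")
  expect_error(generate_outcome(fit, bad, s, 1L), "dimensionality")
})

test_that("a denoiser trained on strong signal reconstructs held-out outcomes", {
  train <- tiny_matrix(n = 250, seed = 31)
  test <- tiny_matrix(n = 120, seed = 32)
  s <- make_schedule(T = 30, t_star = 15)
  fit <- train_denoiser(train, s, epochs = 200, seed = 9)
  h <- forward_noise(test, s, s$t_star, rng_seed = 8)
  yhat <- generate_outcome(fit, h, s, 3L)
  expect_gt(cor(yhat, test[, 3]), 0)
})

test_that("iterated per-step noising agrees with the closed-form marginal", {
  # apply the one-step kernel T times by brute force and compare moments
  s <- make_schedule(T = 12, beta_min = 0.02, beta_max = 0.3, t_star = 6)
  x0 <- 1.7
  n_draws <- 4e4
  set.seed(61)
  v <- rep(x0, n_draws)
  for (t in seq_len(s$T)) {
    b <- s$betas[t]
    v <- sqrt(1 - b) * v + sqrt(b) * rnorm(n_draws)
  }
  ab <- s$alpha_bars[s$T]
  expect_lt(abs(mean(v) - sqrt(ab) * x0), 3 * sqrt((1 - ab) / n_draws))
  expect_lt(abs(var(v) - (1 - ab)), 3 * (1 - ab) * sqrt(2 / n_draws))
})

test_that("standardization is idempotent", {
  m <- tiny_matrix(50, seed = 77)
  st <- cdd:::standardize_stats(m)
  once <- cdd:::apply_standardize(m, st)
  st2 <- cdd:::standardize_stats(once)
  twice <- cdd:::apply_standardize(once, st2)
  expect_equal(once, twice, tolerance = 1e-9)
})
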