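test_that("the Gaussian intervention never reads the observed cause", {
  m <- tiny_matrix(n = 40, seed = 13)
  s <- make_schedule(T = 20, t_star = 10)
  fit <- train_denoiser(m, s, epochs = 40, seed = 2)
  spec <- intervention_spec("H0_gaussian", sample_count = 4, seed = 55)

  slice1 <- data_slice(m, "x", "y")
  m2 <- m
  m2[, "x"] <- sample(m[, "x"])  # permute the cause column
  slice2 <- data_slice(m2, "x", "y")

  y1 <- intervene_and_generate(fit, slice1, s, spec)
  y2 <- intervene_and_generate(fit, slice2, s, spec)
  expect_identical(y1, y2)
  # the input slice is never mutated
  expect_identical(slice1$D, m)
})

test_that("the observed-value intervention is degenerate at t_star = 0", {
  m <- tiny_matrix(n = 25, seed = 14)
  s <- make_schedule(T = 10, t_star = 1)
  s$t_star <- 0L  # degenerate: no noising, empty reverse chain
  fit <- train_denoiser(m, s, epochs = 20, seed = 3)
  slice <- data_slice(m, "x", "y")
  yhat <- intervene_and_generate(
    fit, slice, s, intervention_spec("H1_observed", 3, seed = 1))
  expect_equal(yhat, unname(m[, "y"]), tolerance = 1e-12)
})

test_that("intervention specs validate their inputs", {
  expect_error(intervention_spec("H2_whatever"), "arg")
  expect_error(intervention_spec("H1_observed", sample_count = 0),
               "sample_count")
  m <- tiny_matrix(10)
  expect_error(data_slice(m, "x", "x"), "distinct")
  expect_error(data_slice(m, "x", "nope"), "unknown variable")
})

test_that("Monte-Carlo do-estimates converge to exact enumeration", {
  oracle <- discrete_oracle()
  for (v in c("x1", "x3")) {
    exact <- enumerate_interventional(oracle, v)
    expect_equal(sum(exact), 1, tolerance = 1e-12)
    m <- 2000L
    est <- mc_interventional(oracle, v, m = m, seed = 17)
    se <- sqrt(exact * (1 - exact) / m)
    expect_true(all(abs(est - exact) <= 3 * se + 1e-12))
  }
  expect_error(mc_interventional(oracle, "x9"), "unknown x state")

  # error shrinks at the Monte-Carlo rate: quadrupling draws roughly
  # halves the mean absolute error (averaged over repeats)
  exact <- enumerate_interventional(oracle, "x2")
  err_at <- function(m) mean(sapply(1:20, function(r)
    mean(abs(mc_interventional(oracle, "x2", m = m, seed = 100 + r) - exact))))
  e1 <- err_at(500L); e4 <- err_at(2000L)
  expect_lt(e4 / e1, 0.75)
})

test_that("a y-independent oracle has interventional = observational law", {
  # y depends only on z: intervening on x changes nothing
  y_tab <- array(0, dim = c(2, 2, 2),
                 dimnames = list(c("x1", "x2"), c("z1", "z2"),
                                 c("y1", "y2")))
  y_tab[, "z1", ] <- matrix(c(0.8, 0.2), 2, 2, byrow = TRUE)
  y_tab[, "z2", ] <- matrix(c(0.3, 0.7), 2, 2, byrow = TRUE)
  xz <- rbind(z1 = c(0.9, 0.1), z2 = c(0.2, 0.8))
  colnames(xz) <- c("x1", "x2")
  oracle <- discrete_oracle(c(z1 = 0.5, z2 = 0.5), xz, y_tab)
  expect_equal(enumerate_interventional(oracle, "x1"),
               enumerate_interventional(oracle, "x2"))
  expect_equal(enumerate_interventional(oracle, "x1"),
               observational_marginal(oracle), tolerance = 1e-12)

  # and a copying oracle is fully deterministic under intervention
  y_copy <- array(0, dim = c(2, 2, 2),
                  dimnames = dimnames(y_tab))
  y_copy["x1", , "y1"] <- 1; y_copy["x2", , "y2"] <- 1
  copier <- discrete_oracle(c(z1 = 0.5, z2 = 0.5), xz, y_copy)
  expect_equal(enumerate_interventional(copier, "x1"),
               c(y1 = 1, y2 = 0))
})

test_that("injected noise is empirically independent of the data", {
  set.seed(41)
  n <- 500
  m <- cbind(x = rnorm(n), z = rnorm(n), y = rnorm(n))
  s <- make_schedule(T = 10, t_star = 5)
  rep <- backdoor_sanity_check(data_slice(m, "x", "y"), s, seed = 6)
  expect_true(all(abs(rep$r) < 0.15))
  expect_false(any(rep$flagged))

  # adversarial: a column that IS the injected noise gets flagged
  xi <- cdd:::with_seed(6, rnorm(n))
  m2 <- cbind(x = xi, z = rnorm(n), y = rnorm(n))
  rep2 <- backdoor_sanity_check(data_slice(m2, "x", "y"), s, seed = 6)
  expect_true(rep2$flagged[rep2$column == "x"])

  # two-column slice (empty Z) still reports both columns
  m3 <- m[, c("x", "y")]
  rep3 <- backdoor_sanity_check(data_slice(m3, "x", "y"), s, seed = 6)
  expect_equal(nrow(rep3), 2L)
})
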