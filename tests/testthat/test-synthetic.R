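test_that("simulated networks are seeded DAGs with calibrated density", {
  sim1 <- simulate_grn(n_genes = 10, edge_probability = 0.2,
                       n_samples = 50, seed = 4)
  sim2 <- simulate_grn(n_genes = 10, edge_probability = 0.2,
                       n_samples = 50, seed = 4)
  expect_identical(sim1$expression$values, sim2$expression$values)
  expect_identical(sim1$gold$edges, sim2$gold$edges)

  # edges only run from lower to higher index: acyclic by construction
  src <- as.integer(sub("G", "", sim1$gold$edges[, "source"]))
  tgt <- as.integer(sub("G", "", sim1$gold$edges[, "target"]))
  expect_true(all(src < tgt))

  # edge count across seeds stays inside the binomial 99% envelope
  # (45 candidate slots at p = 0.2 -> mean 9)
  counts <- sapply(1:20, function(s)
    nrow(simulate_grn(n_genes = 10, edge_probability = 0.2,
                      n_samples = 10, seed = s)$gold$edges))
  bounds <- qbinom(c(0.005, 0.995), 45, 0.2)
  expect_true(mean(counts) >= bounds[1] && mean(counts) <= bounds[2])

  expect_error(simulate_grn(edge_probability = 0), "edge_probability")
  expect_error(simulate_grn(coefficient_range = c(0.05, 1)), "near-null")
})

test_that("noiseless linear networks are exact weighted sums of parents", {
  sim <- simulate_grn(n_genes = 6, edge_probability = 0.4, noise_sd = 0,
                      n_samples = 20, seed = 10)
  v <- sim$expression$values
  W <- sim$coefficients
  for (j in seq_len(ncol(v))) {
    parents <- which(W[, j] != 0)
    if (!length(parents)) {
      expect_equal(unname(v[, j]), rep(0, nrow(v)))
    } else {
      expect_equal(v[, j],
                   (v[, parents, drop = FALSE] %*% W[parents, j])[, 1],
                   tolerance = 1e-12)
    }
  }
})

test_that("each node's noise is independent of its parents (ANM structure)", {
  sim <- simulate_grn(n_genes = 8, edge_probability = 0.3, noise_sd = 0.5,
                      n_samples = 400, seed = 6)
  v <- sim$expression$values
  W <- sim$coefficients
  for (j in seq_len(ncol(v))) {
    parents <- which(W[, j] != 0)
    if (!length(parents)) next
    noise <- v[, j] - (v[, parents, drop = FALSE] %*% W[parents, j])[, 1]
    for (p in parents)
      expect_lt(abs(cor(noise, v[, p])), 3 / sqrt(nrow(v)) + 0.05)
  }
})

test_that("the minimal cause-effect pair has the stated moments", {
  # independence at zero effect
  p0 <- simulate_pair(0, n = 400, seed = 3)
  expect_lt(abs(cor(p0$values[, "x"], p0$values[, "y"])), 3 / sqrt(400))

  # plug-in consistency at strong effect
  p9 <- simulate_pair(0.9, n = 1e4, seed = 3)
  expect_equal(cor(p9$values[, "x"], p9$values[, "y"]), 0.9,
               tolerance = 0.02)

  # degenerate deterministic link
  p1 <- simulate_pair(1, n = 50, seed = 3)
  expect_identical(p1$values[, "x"], p1$values[, "y"])

  expect_error(simulate_pair(0.5, n = 5), "n must")
})

test_that("fixtures round-trip through the loaders", {
  sim <- simulate_grn(n_genes = 10, n_samples = 100, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$expression, sim$gold, dir)
  expect_equal(length(readLines(paths[["expression"]])), 101L)

  back <- load_expression(paths[["expression"]])
  expect_equal(back$values, sim$expression$values, tolerance = 1e-12)
  gold <- load_gold_standard(paths[["gold"]], sim$expression$variable_names)
  expect_setequal(paste(gold$edges[, 1], gold$edges[, 2]),
                  paste(sim$gold$edges[, 1], sim$gold$edges[, 2]))

  # empty gold standard writes a valid empty-body file
  empty <- structure(list(
    edges = matrix(character(0), ncol = 2,
                   dimnames = list(NULL, c("source", "target"))),
    negatives = matrix(character(0), ncol = 2),
    variable_names = sim$expression$variable_names), class = "cdd_gold")
  paths2 <- write_fixture(sim$expression, empty, withr::local_tempdir())
  g2 <- load_gold_standard(paths2[["gold"]], sim$expression$variable_names)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("oracle probability tables are validated", {
  expect_error(discrete_oracle(c(z1 = 0.7, z2 = 0.4),
                               rbind(z1 = c(1, 0), z2 = c(0, 1)),
                               array(0.5, c(2, 2, 2))), "sum to 1")
  ok <- discrete_oracle()
  sums <- apply(ok$y_given_xz, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # summation order does not matter: permuted-z enumeration agrees
  perm <- discrete_oracle(ok$z_probs[c("z2", "z1")],
                          ok$x_given_z[c("z2", "z1"), ],
                          ok$y_given_xz[, , ])
  expect_equal(enumerate_interventional(ok, "x2"),
               enumerate_interventional(perm, "x2"), tolerance = 1e-12)
})
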