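# Ground-truth-known synthetic data: additive-noise structural-equation
# networks over a random DAG (the data-generating family the H0/H1
# framework presumes), a minimal two-variable instance, and a small
# discrete Bayesian network whose interventional distribution can be
# enumerated exactly.

#' Simulate an additive-noise gene regulatory network
#'
#' Draws a random DAG (edges only from lower to higher topological index),
#' then samples ancestrally: each node is the coefficient-weighted sum of
#' its parents' link-transformed values plus Gaussian noise. Coefficient
#' magnitudes stay away from zero so every true edge is a genuine signal.
#'
#' @param n_genes number of variables.
#' @param edge_probability probability of each forward pair being an edge,
#'   in (0, 1).
#' @param link_family \code{"linear"} (identity link) or \code{"sigmoid"}
#'   (logistic squashing of the parent value).
#' @param coefficient_range magnitude range (low, high) for edge
#'   coefficients; signs are random. Both ends must be >= 0.2.
#' @param noise_sd standard deviation of each node's additive noise.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return list with \code{expression} (a \code{cdd_expression}),
#'   \code{gold} (a \code{cdd_gold}), and \code{coefficients}
#'   (adjacency-weight matrix, parents in rows).
#' @export
simulate_grn <- function(n_genes = 10L, edge_probability = 0.2,
                         link_family = c("linear", "sigmoid"),
                         coefficient_range = c(0.5, 1.5),
                         noise_sd = 0.5, n_samples = 100L, seed = 1L) {
  link_family <- match.arg(link_family)
  if (!(edge_probability > 0 && edge_probability < 1))
    stop("edge_probability must lie in (0, 1)", call. = FALSE)
  if (min(coefficient_range) < 0.2)
    stop("coefficient magnitudes below 0.2 give near-null edges",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  nms <- paste0("G", seq_len(n_genes))

  with_seed(seed, {
    W <- matrix(0, n_genes, n_genes, dimnames = list(nms, nms))
    for (i in seq_len(n_genes - 1L)) {
      for (j in seq.int(i + 1L, n_genes)) {
        if (stats::runif(1) < edge_probability) {
          mag <- stats::runif(1, coefficient_range[1L], coefficient_range[2L])
          W[i, j] <- mag * sample(c(-1, 1), 1L)
        }
      }
    }
    link <- if (link_family == "linear") identity
            else function(v) 1 / (1 + exp(-v)) - 0.5
    values <- matrix(0, n_samples, n_genes, dimnames = list(NULL, nms))
    for (j in seq_len(n_genes)) {
      parents <- which(W[, j] != 0)
      signal <- if (length(parents))
        link(values[, parents, drop = FALSE]) %*% W[parents, j]
      else 0
      values[, j] <- signal + noise_sd * stats::rnorm(n_samples)
    }
    edges <- which(W != 0, arr.ind = TRUE)
    edge_mat <- cbind(source = nms[edges[, 1L]], target = nms[edges[, 2L]])
    gold <- structure(list(
      edges = edge_mat,
      negatives = matrix(character(0), ncol = 2L,
                         dimnames = list(NULL, c("source", "target"))),
      variable_names = nms), class = "cdd_gold")
    list(expression = new_expression(values, nms), gold = gold,
         coefficients = W)
  })
}

#' Simulate a minimal cause-effect pair
#'
#' x ~ N(0, 1); y = effect * x + sqrt(1 - min(effect^2, 1)) * noise, so y
#' has unit variance for |effect| <= 1 and effect = 0 gives exact
#' independence.
#'
#' @param effect linear effect of x on y.
#' @param n number of samples (>= 10).
#' @param seed integer seed.
#' @return a \code{cdd_expression} with columns \code{x}, \code{y}.
#' @export
simulate_pair <- function(effect, n = 200L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop("n must be >= 10", call. = FALSE)
  with_seed(seed, {
    x <- stats::rnorm(n)
    y <- effect * x + sqrt(1 - min(effect^2, 1)) * stats::rnorm(n)
    new_expression(cbind(x = x, y = y), c("x", "y"))
  })
}

#' Construct a small discrete oracle network
#'
#' Structure: z -> x, z -> y, x -> y, with every conditional probability
#' table exact, so the interventional distribution P(y | do(x)) can be
#' enumerated analytically and used as ground truth for the Monte-Carlo
#' do-estimator.
#'
#' @param z_probs named marginal of the covariate z.
#' @param x_given_z matrix of P(x | z): rows = z states, columns = x
#'   states, each row summing to 1.
#' @param y_given_xz 3-d array of P(y | x, z): dims (x state, z state,
#'   y state), each (x, z) slice summing to 1.
#' @return a \code{cdd_oracle}.
#' @export
discrete_oracle <- function(z_probs = NULL, x_given_z = NULL,
                            y_given_xz = NULL) {
  if (is.null(z_probs)) {
    z_states <- c("z1", "z2")
    x_states <- c("x1", "x2", "x3")
    y_states <- c("y1", "y2", "y3")
    z_probs <- c(z1 = 0.6, z2 = 0.4)
    x_given_z <- rbind(z1 = c(0.5, 0.3, 0.2),
                       z2 = c(0.2, 0.3, 0.5))
    colnames(x_given_z) <- x_states
    y_given_xz <- array(0, dim = c(3L, 2L, 3L),
                        dimnames = list(x_states, z_states, y_states))
    y_given_xz["x1", "z1", ] <- c(0.70, 0.20, 0.10)
    y_given_xz["x1", "z2", ] <- c(0.50, 0.30, 0.20)
    y_given_xz["x2", "z1", ] <- c(0.25, 0.50, 0.25)
    y_given_xz["x2", "z2", ] <- c(0.15, 0.55, 0.30)
    y_given_xz["x3", "z1", ] <- c(0.10, 0.25, 0.65)
    y_given_xz["x3", "z2", ] <- c(0.05, 0.15, 0.80)
  }
  if (abs(sum(z_probs) - 1) > 1e-12)
    stop("z_probs must sum to 1", call. = FALSE)
  if (any(abs(rowSums(x_given_z) - 1) > 1e-12))
    stop("each row of x_given_z must sum to 1", call. = FALSE)
  y_sums <- apply(y_given_xz, c(1L, 2L), sum)
  if (any(abs(y_sums - 1) > 1e-12))
    stop("each P(y | x, z) table must sum to 1", call. = FALSE)
  if (!setequal(rownames(x_given_z), names(z_probs)))
    stop("x_given_z rows must match z states", call. = FALSE)
  structure(list(z_probs = z_probs,
                 x_given_z = x_given_z[names(z_probs), , drop = FALSE],
                 y_given_xz = y_given_xz),
            class = "cdd_oracle")
}

#' Exact interventional distribution on the discrete oracle
#'
#' Backdoor enumeration: P(y | do(x = value)) = sum_z P(z) P(y | x, z).
#' The intervention severs z's influence on x, so z keeps its marginal.
#'
#' @param oracle a \code{cdd_oracle}.
#' @param value an x state name.
#' @return named numeric vector over y states, summing to 1.
#' @export
enumerate_interventional <- function(oracle, value) {
  stopifnot(inherits(oracle, "cdd_oracle"))
  if (!value %in% colnames(oracle$x_given_z))
    stop("unknown x state: ", value, call. = FALSE)
  z_states <- names(oracle$z_probs)
  y_states <- dimnames(oracle$y_given_xz)[[3L]]
  out <- stats::setNames(numeric(length(y_states)), y_states)
  for (z in z_states)
    out <- out + oracle$z_probs[[z]] * oracle$y_given_xz[value, z, ]
  out
}

#' Observational marginal of y on the discrete oracle
#'
#' P(y) = sum_z sum_x P(z) P(x | z) P(y | x, z); useful as the contrast
#' against the interventional distribution.
#'
#' @param oracle a \code{cdd_oracle}.
#' @return named numeric vector over y states.
#' @export
observational_marginal <- function(oracle) {
  stopifnot(inherits(oracle, "cdd_oracle"))
  z_states <- names(oracle$z_probs)
  x_states <- colnames(oracle$x_given_z)
  y_states <- dimnames(oracle$y_given_xz)[[3L]]
  out <- stats::setNames(numeric(length(y_states)), y_states)
  for (z in z_states)
    for (x in x_states)
      out <- out + oracle$z_probs[[z]] * oracle$x_given_z[z, x] *
        oracle$y_given_xz[x, z, ]
  out
}

#' Write a benchmark-style fixture to disk
#'
#' Emits the expression TSV and the gold-standard edge list (every true
#' edge with label 1) in the loader dialects.
#'
#' @param expression a \code{cdd_expression}.
#' @param gold a \code{cdd_gold}.
#' @param directory output directory (created if missing).
#' @return named character vector of the two file paths.
#' @export
write_fixture <- function(expression, gold, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  expr_path <- file.path(directory, "expression.tsv")
  gold_path <- file.path(directory, "gold_standard.tsv")
  write_expression(expression, expr_path)
  lines <- character(0)
  if (nrow(gold$edges))
    lines <- sprintf("%s\t%s\t1", gold$edges[, "source"],
                     gold$edges[, "target"])
  writeLines(lines, gold_path)
  c(expression = expr_path, gold = gold_path)
}
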