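# The H0/H1 decision machinery: K-fold splitting, distances between
# generated and observed outcomes, the acceptance rule, and the full
# per-edge cross-validated test.

#' Split samples into K folds
#'
#' Random permutation followed by round-robin assignment, so fold sizes
#' differ by at most one. Deterministic per seed.
#'
#' @param sample_count number of samples.
#' @param k number of folds, 2 <= k <= sample_count.
#' @param seed integer seed.
#' @return a \code{cdd_folds}: list with \code{k}, \code{assignments}
#'   (fold index per sample, 1..k), \code{seed}.
#' @export
kfold_split <- function(sample_count, k, seed = 1L) {
  sample_count <- as.integer(sample_count); k <- as.integer(k)
  if (is.na(k) || k < 2L || k > sample_count)
    stop("k must satisfy 2 <= k <= sample_count", call. = FALSE)
  perm <- with_seed(seed, sample.int(sample_count))
  assignments <- integer(sample_count)
  assignments[perm] <- rep_len(seq_len(k), sample_count)
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "cdd_folds")
}

# Default fold count mirrors the benchmark practice of 3 or 5 folds
# depending on dataset size.
default_folds <- function(sample_count) {
  if (sample_count < 4L)
    stop("need at least 4 samples to cross-validate", call. = FALSE)
  if (sample_count >= 15L) 5L else 3L
}

#' Distance between generated and observed outcome vectors
#'
#' \describe{
#'   \item{mse}{mean squared difference.}
#'   \item{kl}{Kullback-Leibler divergence between Gaussian fits
#'     (mean/sd) of the two vectors; variances are floored at 1e-8 with a
#'     logged warning.}
#'   \item{hsic}{1 / (1 + HSIC_b), where HSIC_b is the biased
#'     Hilbert-Schmidt independence statistic with RBF kernels and
#'     median-heuristic bandwidths: stronger dependence between generated
#'     and observed values gives a smaller distance.}
#' }
#'
#' @param generated,observed numeric vectors of equal length >= 2.
#' @param metric one of \code{"mse"}, \code{"kl"}, \code{"hsic"}.
#' @return a nonnegative scalar.
#' @export
edge_distance <- function(generated, observed,
                          metric = c("mse", "kl", "hsic")) {
  metric <- match.arg(metric)
  if (length(generated) != length(observed))
    stop("generated and observed vectors differ in length", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 values to compute a distance", call. = FALSE)
  switch(metric,
    mse = mean((generated - observed)^2),
    kl = {
      v1 <- stats::var(generated); v2 <- stats::var(observed)
      if (v1 < 1e-8 || v2 < 1e-8)
        cdd_log("warning",
                "near-zero variance in KL distance; flooring at 1e-8")
      v1 <- max(v1, 1e-8); v2 <- max(v2, 1e-8)
      m1 <- mean(generated); m2 <- mean(observed)
      0.5 * (log(v2 / v1) + (v1 + (m1 - m2)^2) / v2 - 1)
    },
    hsic = 1 / (1 + hsic_biased(generated, observed))
  )
}

# Biased HSIC statistic, definitional form: HSIC_b = tr(K H L H) / n^2
# with H the centering matrix and RBF kernels at the median-heuristic
# bandwidth of each vector.
hsic_biased <- function(a, b) {
  n <- length(a)
  K <- rbf_gram(a)
  L <- rbf_gram(b)
  Kc <- K - rowMeans(K)
  Kc <- sweep(Kc, 2L, colMeans(Kc), "-")
  sum(Kc * L) / n^2
}

rbf_gram <- function(v) {
  d2 <- outer(v, v, "-")^2
  pos <- d2[upper.tri(d2)]
  pos <- pos[pos > 0]
  sigma2 <- if (length(pos)) stats::median(pos) else 1
  if (sigma2 < 1e-12) sigma2 <- 1e-12
  exp(-d2 / (2 * sigma2))
}

#' Accept H0 or H1 from the two pooled distances
#'
#' H1 (x causes y) is accepted only under the strict inequality
#' d_H1 < d_H0; ties and the reverse inequality accept H0. The continuous
#' confidence score (d_H0 - d_H1) / (d_H0 + d_H1 + 1e-12) lies in (-1, 1)
#' and is positive exactly when H1 is accepted.
#'
#' @param d_H1 pooled distance between the H1 generation and the observed
#'   outcome.
#' @param d_H0 pooled distance under the Gaussian-noise intervention.
#' @return list with \code{decision} ("H0" or "H1") and \code{score}.
#' @export
decide_edge <- function(d_H1, d_H0) {
  if (!is.finite(d_H1) || !is.finite(d_H0))
    stop("distances must be finite", call. = FALSE)
  score <- (d_H0 - d_H1) / (d_H0 + d_H1 + 1e-12)
  list(decision = if (d_H1 < d_H0) "H1" else "H0", score = score)
}

#' Test one candidate directed edge by K-fold cross-validation
#'
#' For each fold the denoiser is trained on the training portion (or an
#' already-trained fold model is reused), both interventions are run on
#' the held-out portion, and the generated outcomes are compared with the
#' observed ones. Distances are pooled by summation across folds and the
#' acceptance rule applied once to the pooled values. Standardization uses
#' training-fold statistics on both portions, so no test information leaks
#' into the model.
#'
#' @param data a \code{cdd_expression} (or numeric matrix with column
#'   names).
#' @param x_name,y_name candidate cause and outcome.
#' @param folds a \code{cdd_folds}; by default built from
#'   \code{config$folds} (or 5 folds when >= 15 samples, else 3).
#' @param schedule a \code{cdd_schedule}; by default built from the config.
#' @param config list of options; see [cdd_config()].
#' @param models optional list of pre-trained fold denoisers (index =
#'   fold), as produced inside [infer_network()].
#' @return a \code{cdd_edge}: list with \code{x_name}, \code{y_name},
#'   \code{d_H1}, \code{d_H0}, \code{decision}, \code{score},
#'   \code{per_fold} (matrix of per-fold distances).
#' @export
test_edge <- function(data, x_name, y_name, folds = NULL, schedule = NULL,
                      config = cdd_config(), models = NULL) {
  values <- expression_values(data)
  if (identical(x_name, y_name))
    stop("cause and outcome must be distinct variables", call. = FALSE)
  config <- cdd_config(config)
  if (is.null(schedule)) schedule <- config_schedule(config)
  n <- nrow(values)
  if (is.null(folds)) {
    k <- config$folds %||% default_folds(n)
    folds <- kfold_split(n, k, seed = config$seed)
  }
  per_fold <- matrix(NA_real_, nrow = folds$k, ncol = 2L,
                     dimnames = list(NULL, c("d_H1", "d_H0")))
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$assignments == f)
    train_idx <- which(folds$assignments != f)
    stats_f <- standardize_stats(values[train_idx, , drop = FALSE])
    if (any(apply(values[train_idx, , drop = FALSE], 2L, stats::sd) < 1e-8))
      cdd_log("warning", "constant column in training fold %d; sd floored", f)
    train_std <- apply_standardize(values[train_idx, , drop = FALSE], stats_f)
    test_std <- apply_standardize(values[test_idx, , drop = FALSE], stats_f)
    model <- if (!is.null(models)) models[[f]] else
      train_denoiser(train_std, schedule,
                     epochs = config$epochs,
                     seed = derive_seed(config$seed, 7L, f),
                     learning_rate = config$learning_rate,
                     width = config$hidden_width)
    slice <- data_slice(test_std, x_name, y_name)
    iv_seed <- config$intervention_seed %||%
      derive_seed(config$seed, 11L, f, slice$x_index, slice$y_index)
    y_obs <- test_std[, slice$y_index]
    yhat <- lapply(c("H1_observed", "H0_gaussian"), function(mode) {
      spec <- intervention_spec(mode, sample_count = config$draws,
                                seed = iv_seed)
      intervene_and_generate(model, slice, schedule, spec,
                             deterministic = config$deterministic,
                             mask_y = config$mask_y)
    })
    per_fold[f, "d_H1"] <- edge_distance(yhat[[1L]], y_obs, config$metric)
    per_fold[f, "d_H0"] <- edge_distance(yhat[[2L]], y_obs, config$metric)
  }
  d_H1 <- sum(per_fold[, "d_H1"]); d_H0 <- sum(per_fold[, "d_H0"])
  verdict <- decide_edge(d_H1, d_H0)
  structure(list(x_name = x_name, y_name = y_name,
                 d_H1 = d_H1, d_H0 = d_H0,
                 decision = verdict$decision, score = verdict$score,
                 per_fold = per_fold),
            class = "cdd_edge")
}

#' @export
print.cdd_edge <- function(x, ...) {
  cat(sprintf("%s -> %s: %s (score %.4f; d_H1 %.4f, d_H0 %.4f, %d folds)\n",
              x$x_name, x$y_name, x$decision, x$score, x$d_H1, x$d_H0,
              nrow(x$per_fold)))
  invisible(x)
}

expression_values <- function(data) {
  if (inherits(data, "cdd_expression")) return(data$values)
  m <- as.matrix(data)
  if (is.null(colnames(m)))
    stop("data must have variable (column) names", call. = FALSE)
  m
}

#' Default configuration for network inference
#'
#' Fields mirror the command-line flags. Unknown fields are rejected.
#'
#' @param config optional list of overrides (possibly already a config).
#' @return a complete named list of options.
#' @export
cdd_config <- function(config = list()) {
  if (isTRUE(attr(config, "cdd_complete"))) return(config)
  defaults <- list(
    timesteps = 50L, beta_min = 1e-4, beta_max = 0.02,
    hidden_step = NULL,          # default timesteps / 2
    epochs = 300L, learning_rate = 1e-3, hidden_width = 64L,
    folds = NULL,                # default 5 (>= 15 samples) else 3
    metric = "mse", seed = 1L, prefilter = 0,
    draws = 20L, deterministic = TRUE, mask_y = FALSE,
    per_edge_training = FALSE, intervention_seed = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  out$metric <- match.arg(out$metric, c("mse", "kl", "hsic"))
  attr(out, "cdd_complete") <- TRUE
  out
}

config_schedule <- function(config) {
  t_star <- config$hidden_step %||% max(1L, as.integer(config$timesteps) %/% 2L)
  make_schedule(T = config$timesteps, beta_min = config$beta_min,
                beta_max = config$beta_max, t_star = t_star)
}
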