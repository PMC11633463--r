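# The diffusion engine: a fixed forward (noising) Markov process and a
# learned backward (denoising) process over the joint variable vector
# D = (x, Z, y). The forward kernel is Gaussian with a fixed variance
# schedule (the "artificially given" parameters theta_1); the backward
# process is realized by a small fully connected noise-prediction network
# (theta_2) trained with the standard denoising objective: predict the
# injected noise from the noised vector and the step index.

#' Build a noise schedule
#'
#' Per-step variances beta_t are linearly interpolated between
#' \code{beta_min} and \code{beta_max}; the cumulative signal fraction
#' alpha_bar_t = prod(1 - beta_s) for s <= t is strictly decreasing.
#' \code{t_star} is the hidden-layer step at which interventions act.
#'
#' @param T number of diffusion steps (>= 2).
#' @param beta_min,beta_max first/last per-step noise variance, in (0, 1).
#' @param t_star intervention step, in 1..T. Default \code{T/2}, where the
#'   hidden state retains partial signal so interventions stay meaningful.
#' @return a \code{cdd_schedule}: list with \code{T}, \code{betas},
#'   \code{alpha_bars}, \code{t_star}.
#' @export
make_schedule <- function(T = 50L, beta_min = 1e-4, beta_max = 0.02,
                          t_star = max(1L, T %/% 2L)) {
  T <- as.integer(T)
  if (is.na(T) || T < 2L) stop("T must be an integer >= 2", call. = FALSE)
  if (!(beta_min > 0 && beta_min <= beta_max && beta_max < 1))
    stop("need 0 < beta_min <= beta_max < 1", call. = FALSE)
  t_star <- as.integer(t_star)
  if (is.na(t_star) || t_star < 1L || t_star > T)
    stop("t_star must lie in 1..T", call. = FALSE)
  betas <- seq(beta_min, beta_max, length.out = T)
  structure(list(T = T, betas = betas, alpha_bars = cumprod(1 - betas),
                 t_star = t_star),
            class = "cdd_schedule")
}

#' @export
print.cdd_schedule <- function(x, ...) {
  cat(sprintf(
    "Noise schedule: T=%d, beta in [%g, %g], t_star=%d (alpha_bar=%.3f), alpha_bar_T=%.4f\n",
    x$T, x$betas[1L], x$betas[x$T], x$t_star,
    x$alpha_bars[x$t_star], x$alpha_bars[x$T]))
  invisible(x)
}

# alpha_bar with the t = 0 convention alpha_bar_0 = 1 (identity).
alpha_bar_at <- function(schedule, t) {
  if (t == 0L) 1 else schedule$alpha_bars[[t]]
}

#' Apply the forward (noising) process at step t
#'
#' Uses the closed-form marginal of the Gaussian forward chain:
#' h = sqrt(alpha_bar_t) * v + sqrt(1 - alpha_bar_t) * xi, xi ~ N(0, I),
#' applied coordinate-wise to every column, so the cause, outcome and
#' covariates are all noised by the same map. t = 0 is the identity.
#'
#' @param values numeric matrix (samples x variables), standardized.
#' @param schedule a \code{cdd_schedule}.
#' @param t step in 0..T.
#' @param rng_seed integer seed for the injected noise.
#' @return a \code{cdd_hidden}: list with \code{H} (noised matrix) and
#'   \code{t}.
#' @export
forward_noise <- function(values, schedule, t, rng_seed = 1L) {
  stopifnot(inherits(schedule, "cdd_schedule"))
  values <- as.matrix(values)
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t > schedule$T)
    stop("t must lie in 0..T", call. = FALSE)
  if (t == 0L) return(structure(list(H = values, t = 0L), class = "cdd_hidden"))
  ab <- alpha_bar_at(schedule, t)
  xi <- with_seed(rng_seed,
                  matrix(stats::rnorm(length(values)), nrow = nrow(values)))
  structure(list(H = sqrt(ab) * values + sqrt(1 - ab) * xi, t = t),
            class = "cdd_hidden")
}

# Noise-prediction network -------------------------------------------------
#
# Architecture: input = noised vector (d) ++ sinusoidal embedding of t
# (TIME_EMB dims); two tanh hidden layers of `width` units; linear output
# of d units (the predicted noise).

TIME_EMB <- 8L

time_embedding <- function(t, T) {
  # t may be a vector; returns length(t) x TIME_EMB
  k <- TIME_EMB %/% 2L
  freqs <- 10000^(-(seq_len(k) - 1L) / k)
  ang <- outer(t / T, freqs * pi)
  cbind(sin(ang), cos(ang))
}

init_mlp <- function(d_in, d_out, width) {
  glorot <- function(nin, nout) matrix(stats::rnorm(nin * nout,
                                                    sd = sqrt(2 / (nin + nout))),
                                       nrow = nin)
  list(W1 = glorot(d_in, width),  b1 = numeric(width),
       W2 = glorot(width, width), b2 = numeric(width),
       W3 = glorot(width, d_out), b3 = numeric(d_out))
}

mlp_forward <- function(par, X) {
  A1 <- tanh(sweep(X %*% par$W1, 2L, par$b1, "+"))
  A2 <- tanh(sweep(A1 %*% par$W2, 2L, par$b2, "+"))
  out <- sweep(A2 %*% par$W3, 2L, par$b3, "+")
  list(A1 = A1, A2 = A2, out = out)
}

mlp_grad <- function(par, X, fwd, dOut) {
  dA2 <- dOut %*% t(par$W3) * (1 - fwd$A2^2)
  dA1 <- dA2 %*% t(par$W2) * (1 - fwd$A1^2)
  list(W1 = t(X) %*% dA1,       b1 = colSums(dA1),
       W2 = t(fwd$A1) %*% dA2,  b2 = colSums(dA2),
       W3 = t(fwd$A2) %*% dOut, b3 = colSums(dOut))
}

#' Train the denoiser
#'
#' Fits the backward-process parameters by minimizing the mean squared
#' error between the injected forward noise and the network's prediction
#' at steps sampled uniformly from 1..T, full-batch Adam. Deterministic
#' for a fixed seed, data and configuration.
#'
#' @param train_matrix numeric matrix (samples x variables), standardized
#'   with its own (training-fold) statistics.
#' @param schedule a \code{cdd_schedule}.
#' @param epochs training epochs (>= 1).
#' @param seed integer seed controlling initialization and noise draws.
#' @param learning_rate Adam step size.
#' @param width hidden-layer width.
#' @return a \code{cdd_denoiser}: list with \code{params},
#'   \code{training_log} (per-epoch loss), \code{seed}, \code{d},
#'   \code{config}.
#' @export
train_denoiser <- function(train_matrix, schedule, epochs = 300L, seed = 1L,
                           learning_rate = 1e-3, width = 64L) {
  stopifnot(inherits(schedule, "cdd_schedule"))
  train_matrix <- as.matrix(train_matrix)
  n <- nrow(train_matrix); d <- ncol(train_matrix)
  if (n < 2L) stop("need at least 2 training samples", call. = FALSE)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L)
    stop("epochs must be a positive integer", call. = FALSE)

  with_seed(seed, {
    par <- init_mlp(d + TIME_EMB, d, width)
    m_adam <- lapply(par, function(p) p * 0)
    v_adam <- lapply(par, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    log_loss <- numeric(epochs)
    step <- 0L
    for (ep in seq_len(epochs)) {
      t_idx <- sample.int(schedule$T, n, replace = TRUE)
      ab <- schedule$alpha_bars[t_idx]
      noise <- matrix(stats::rnorm(n * d), nrow = n)
      H <- sqrt(ab) * train_matrix + sqrt(1 - ab) * noise
      X <- cbind(H, time_embedding(t_idx, schedule$T))
      fwd <- mlp_forward(par, X)
      resid <- fwd$out - noise
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep),
             call. = FALSE)
      log_loss[ep] <- loss
      grad <- mlp_grad(par, X, fwd, 2 * resid / length(resid))
      step <- step + 1L
      for (nm in names(par)) {
        m_adam[[nm]] <- b1 * m_adam[[nm]] + (1 - b1) * grad[[nm]]
        v_adam[[nm]] <- b2 * v_adam[[nm]] + (1 - b2) * grad[[nm]]^2
        mh <- m_adam[[nm]] / (1 - b1^step)
        vh <- v_adam[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    structure(list(params = par, training_log = log_loss, seed = seed, d = d,
                   config = list(epochs = epochs,
                                 learning_rate = learning_rate,
                                 width = width, T = schedule$T)),
              class = "cdd_denoiser")
  })
}

#' @export
print.cdd_denoiser <- function(x, ...) {
  cat(sprintf(
    "Denoiser: %d variables, width %d, %d epochs (loss %.4f -> %.4f), seed %d\n",
    x$d, x$config$width, x$config$epochs,
    x$training_log[1L], x$training_log[length(x$training_log)], x$seed))
  invisible(x)
}

# Predicted noise for a batch of hidden vectors at a single step t.
predict_noise <- function(model, H, t) {
  if (ncol(H) != model$d)
    stop(sprintf("hidden state has %d coordinates but model expects %d",
                 ncol(H), model$d), call. = FALSE)
  X <- cbind(H, time_embedding(rep.int(t, nrow(H)), model$config$T))
  mlp_forward(model$params, X)$out
}

# Reverse the chain from step t0 down to 0, returning the full matrix.
# With deterministic = TRUE each transition uses its posterior mean only.
reverse_chain <- function(model, H, t0, schedule, deterministic = TRUE) {
  if (t0 == 0L) return(H)
  for (t in seq.int(t0, 1L)) {
    beta <- schedule$betas[[t]]
    ab <- schedule$alpha_bars[[t]]
    ab_prev <- alpha_bar_at(schedule, t - 1L)
    eps_hat <- predict_noise(model, H, t)
    H <- (H - beta / sqrt(1 - ab) * eps_hat) / sqrt(1 - beta)
    if (!deterministic && t > 1L) {
      sigma <- sqrt(beta * (1 - ab_prev) / (1 - ab))
      H <- H + sigma * matrix(stats::rnorm(length(H)), nrow = nrow(H))
    }
  }
  H
}

#' Generate outcome values from a hidden state
#'
#' Runs the learned reverse process from the hidden state's step down to 0
#' on all coordinates jointly and returns the outcome coordinate, one value
#' per row. A hidden state at step 0 is returned unchanged (empty chain).
#'
#' @param model a \code{cdd_denoiser}.
#' @param hidden a \code{cdd_hidden} at step \code{schedule$t_star}.
#' @param schedule a \code{cdd_schedule}.
#' @param y_index column index of the outcome coordinate.
#' @param deterministic if TRUE (default) reverse transitions use their
#'   mean, so repeated calls agree exactly.
#' @return numeric vector of generated outcome values.
#' @export
generate_outcome <- function(model, hidden, schedule, y_index,
                             deterministic = TRUE) {
  stopifnot(inherits(model, "cdd_denoiser"), inherits(hidden, "cdd_hidden"),
            inherits(schedule, "cdd_schedule"))
  if (ncol(hidden$H) != model$d)
    stop("hidden state dimensionality does not match the model", call. = FALSE)
  out <- reverse_chain(model, hidden$H, hidden$t, schedule, deterministic)
  out[, y_index]
}
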