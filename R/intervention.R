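# Do-calculus on the hidden layer. Interventions cannot act on the raw
# variables (the backdoor criterion generally fails there), so the do
# operation replaces the candidate cause's hidden-layer coordinate h_x —
# which depends only on the input data and injected independent noise —
# before running the learned reverse process. The interventional
# distribution P(y | do(h_x)) = sum_x P(y | h_x, x) P(x) is approximated
# by Monte-Carlo draws of the intervention value, averaged per test sample.

#' Describe an intervention
#'
#' @param mode \code{"H1_observed"} (intervene with each test sample's own
#'   observed cause value) or \code{"H0_gaussian"} (intervene with standard
#'   normal noise, severing any dependence on the factual cause).
#' @param sample_count number of Monte-Carlo generation draws per test
#'   sample (>= 1); generated outcomes are averaged across draws.
#' @param seed integer seed for all noise consumed by the intervention.
#' @return a \code{cdd_intervention} spec.
#' @export
intervention_spec <- function(mode = c("H1_observed", "H0_gaussian"),
                              sample_count = 20L, seed = 1L) {
  mode <- match.arg(mode)
  sample_count <- as.integer(sample_count)
  if (is.na(sample_count) || sample_count < 1L)
    stop("sample_count must be >= 1", call. = FALSE)
  structure(list(mode = mode, sample_count = sample_count,
                 seed = as.integer(seed)),
            class = "cdd_intervention")
}

#' Build one candidate edge's view of a (standardized) data matrix
#'
#' @param values standardized numeric matrix with column names.
#' @param x_name,y_name candidate cause and outcome; must differ.
#' @return a \code{cdd_slice}: list with \code{D}, \code{x_index},
#'   \code{y_index}, \code{z_indices}, \code{x_name}, \code{y_name}.
#' @export
data_slice <- function(values, x_name, y_name) {
  values <- as.matrix(values)
  nms <- colnames(values)
  if (is.null(nms)) stop("matrix must have column names", call. = FALSE)
  if (identical(x_name, y_name))
    stop("cause and outcome must be distinct variables", call. = FALSE)
  xi <- match(x_name, nms); yi <- match(y_name, nms)
  if (is.na(xi) || is.na(yi))
    stop("unknown variable name: ", if (is.na(xi)) x_name else y_name,
         call. = FALSE)
  structure(list(D = values, x_index = xi, y_index = yi,
                 z_indices = setdiff(seq_along(nms), c(xi, yi)),
                 x_name = x_name, y_name = y_name),
            class = "cdd_slice")
}

#' Intervene on the hidden layer and generate outcome estimates
#'
#' For each test sample: draw the intervention value (the sample's observed
#' cause under H1, a fresh standard-normal value under H0), push it through
#' the forward process to the hidden step, combine with the forward-noised
#' outcome and covariates of that sample, and run the reverse process to
#' regenerate the outcome. The \code{sample_count} draws per sample are
#' averaged, realizing the Monte-Carlo marginalization over the
#' intervention distribution. Identical seeds reuse identical forward noise
#' for the outcome/covariate coordinates in both modes, so the two
#' hypotheses are compared on common random numbers. Under
#' \code{H0_gaussian} the observed cause column is never read.
#'
#' @param model a \code{cdd_denoiser} trained on the disjoint training fold.
#' @param slice a \code{cdd_slice} over the standardized test fold.
#' @param schedule a \code{cdd_schedule}; interventions act at
#'   \code{schedule$t_star}.
#' @param spec a \code{cdd_intervention}.
#' @param deterministic use mean-only reverse transitions (default TRUE).
#' @param mask_y replace the outcome's hidden coordinate with pure noise,
#'   blocking information leaking from the observed outcome (default FALSE,
#'   matching the algorithm as published).
#' @return numeric vector of generated outcomes, one per test sample.
#' @export
intervene_and_generate <- function(model, slice, schedule, spec,
                                   deterministic = TRUE, mask_y = FALSE) {
  stopifnot(inherits(model, "cdd_denoiser"), inherits(slice, "cdd_slice"),
            inherits(schedule, "cdd_schedule"),
            inherits(spec, "cdd_intervention"))
  n <- nrow(slice$D); d <- ncol(slice$D)
  if (n < 1L) stop("test fold has no samples", call. = FALSE)
  m <- spec$sample_count
  t_star <- schedule$t_star
  ab <- alpha_bar_at(schedule, t_star)
  xi_idx <- slice$x_index; yi_idx <- slice$y_index

  with_seed(spec$seed, {
    # shared forward noise for all coordinates, identical across modes
    eps <- matrix(stats::rnorm(m * n * d), nrow = m * n, ncol = d)
    # intervention values: observed x (repeated per draw) or fresh noise
    x_int <- if (spec$mode == "H1_observed") {
      rep(slice$D[, xi_idx], times = m)
    } else {
      stats::rnorm(m * n)
    }
    y_mask <- if (mask_y) stats::rnorm(m * n) else NULL

    base <- slice$D[rep(seq_len(n), times = m), , drop = FALSE]
    base[, xi_idx] <- x_int
    H <- sqrt(ab) * base + sqrt(1 - ab) * eps
    if (!is.null(y_mask)) H[, yi_idx] <- y_mask

    hidden <- structure(list(H = H, t = t_star), class = "cdd_hidden")
    yhat <- generate_outcome(model, hidden, schedule, yi_idx,
                             deterministic = deterministic)
    # average the m draws per test sample
    colMeans(matrix(yhat, nrow = m, byrow = TRUE))
  })
}

#' Empirical backdoor check: injected noise is independent of the data
#'
#' The hidden layer's validity as an intervention locus rests on the
#' forward noise being independent of every observed column. This check
#' draws fresh forward noise and reports its empirical correlation with
#' each column, flagging any absolute correlation above the threshold.
#' It is a diagnostic, not a proof.
#'
#' @param slice a \code{cdd_slice}.
#' @param schedule a \code{cdd_schedule} (records the step checked).
#' @param seed integer seed for the noise draw.
#' @param threshold flag level for |r| (default 0.15).
#' @return data.frame with columns \code{column}, \code{r}, \code{flagged}.
#' @export
backdoor_sanity_check <- function(slice, schedule, seed = 1L,
                                  threshold = 0.15) {
  stopifnot(inherits(slice, "cdd_slice"), inherits(schedule, "cdd_schedule"))
  n <- nrow(slice$D)
  xi <- with_seed(seed, stats::rnorm(n))
  r <- apply(slice$D, 2L, function(col) {
    if (stats::sd(col) < 1e-12) return(0)
    stats::cor(xi, col)
  })
  out <- data.frame(column = colnames(slice$D), r = as.numeric(r),
                    flagged = abs(r) > threshold, row.names = NULL)
  if (any(out$flagged))
    cdd_log("warning", "backdoor check flagged columns: %s",
            paste(out$column[out$flagged], collapse = ", "))
  out
}

#' Monte-Carlo interventional distribution on a discrete network
#'
#' Estimates P(y | do(x = value)) on a discrete oracle network by sampling
#' the covariate from its marginal and the outcome from its conditional
#' table, m draws. Converges to the exact backdoor enumeration
#' ([enumerate_interventional()]) at the usual 1/sqrt(m) Monte-Carlo rate.
#' This validates the sampling-based do-estimator itself, independently of
#' any trained model.
#'
#' @param oracle a \code{cdd_oracle} (see [discrete_oracle()]).
#' @param value an x state name.
#' @param m number of draws.
#' @param seed integer seed.
#' @return named numeric vector of estimated probabilities over y states.
#' @export
mc_interventional <- function(oracle, value, m = 2000L, seed = 1L) {
  stopifnot(inherits(oracle, "cdd_oracle"))
  if (!value %in% colnames(oracle$x_given_z))
    stop("unknown x state: ", value, call. = FALSE)
  z_states <- names(oracle$z_probs)
  y_states <- dimnames(oracle$y_given_xz)[[3L]]
  with_seed(seed, {
    z_draw <- sample(z_states, m, replace = TRUE, prob = oracle$z_probs)
    counts <- stats::setNames(numeric(length(y_states)), y_states)
    for (z in z_states) {
      k <- sum(z_draw == z)
      if (k == 0L) next
      probs <- oracle$y_given_xz[value, z, ]
      y_draw <- sample(y_states, k, replace = TRUE, prob = probs)
      tab <- table(factor(y_draw, levels = y_states))
      counts <- counts + as.numeric(tab)
    }
    counts / m
  })
}
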