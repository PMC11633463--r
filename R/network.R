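# Network assembly: enumerate ordered candidate pairs, run the edge test
# for each, and evaluate decisions and scores against a gold standard.

#' Enumerate candidate ordered pairs
#'
#' All ordered pairs (x, y), x != y, whose absolute Pearson correlation
#' reaches \code{prefilter_r}; 0 keeps all n(n-1) pairs. The prefilter
#' plays the role of an initial correlation network from which edges are
#' then tested causally.
#'
#' @param data a \code{cdd_expression} or named numeric matrix.
#' @param prefilter_r absolute-correlation threshold in [0, 1].
#' @return data.frame with columns \code{source}, \code{target}.
#' @export
candidate_pairs <- function(data, prefilter_r = 0) {
  values <- expression_values(data)
  if (!is.numeric(prefilter_r) || prefilter_r < 0 || prefilter_r > 1)
    stop("prefilter_r must lie in [0, 1]", call. = FALSE)
  nms <- colnames(values)
  grid <- expand.grid(target = nms, source = nms,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  # source-major order by input variable position
  grid <- grid[order(match(grid$source, nms), match(grid$target, nms)), ,
               drop = FALSE]
  rownames(grid) <- NULL
  if (prefilter_r > 0) {
    cm <- suppressWarnings(abs(stats::cor(values)))
    cm[!is.finite(cm)] <- 0
    keep <- mapply(function(s, t) cm[s, t] >= prefilter_r,
                   grid$source, grid$target)
    grid <- grid[keep, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

#' Infer a directed causal network
#'
#' Trains one denoiser per cross-validation fold on the full variable set
#' (shared across all candidate edges, since the generative model covers
#' the joint distribution), then runs the H0/H1 edge test for every
#' candidate ordered pair. A failing pair is logged and skipped, not fatal.
#'
#' @param data a \code{cdd_expression} or named numeric matrix.
#' @param config list of options; see [cdd_config()].
#' @return a \code{cdd_network}: list with \code{results} (list of
#'   \code{cdd_edge}), \code{variable_names}, \code{config_snapshot}.
#' @export
infer_network <- function(data, config = cdd_config()) {
  values <- expression_values(data)
  config <- cdd_config(config)
  n <- nrow(values)
  k <- config$folds %||% default_folds(n)
  if (n < 2L * k)
    stop(sprintf("need at least %d samples for %d folds", 2L * k, k),
         call. = FALSE)
  schedule <- config_schedule(config)
  folds <- kfold_split(n, k, seed = config$seed)

  models <- NULL
  if (!config$per_edge_training) {
    cdd_log("info", "training %d fold denoisers (%d epochs each)",
            k, config$epochs)
    models <- lapply(seq_len(k), function(f) {
      train_idx <- which(folds$assignments != f)
      stats_f <- standardize_stats(values[train_idx, , drop = FALSE])
      train_denoiser(apply_standardize(values[train_idx, , drop = FALSE],
                                       stats_f),
                     schedule, epochs = config$epochs,
                     seed = derive_seed(config$seed, 7L, f),
                     learning_rate = config$learning_rate,
                     width = config$hidden_width)
    })
  }

  pairs <- candidate_pairs(values, config$prefilter)
  results <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch(
      test_edge(values, pairs$source[i], pairs$target[i],
                folds = folds, schedule = schedule, config = config,
                models = models),
      error = function(e) {
        cdd_log("warning", "edge %s -> %s failed: %s",
                pairs$source[i], pairs$target[i], conditionMessage(e))
        NULL
      })
    results[[i]] <- res
    if (!is.null(res))
      cdd_log("debug", "edge %s -> %s: %s (score %.3f)",
              res$x_name, res$y_name, res$decision, res$score)
  }
  results <- results[!vapply(results, is.null, TRUE)]
  cdd_log("info", "evaluated %d ordered pairs, %d H1 decisions",
          length(results),
          sum(vapply(results, function(r) r$decision == "H1", TRUE)))
  structure(list(results = results, variable_names = colnames(values),
                 config_snapshot = config),
            class = "cdd_network")
}

#' @export
as.data.frame.cdd_network <- function(x, ...) {
  if (!length(x$results))
    return(data.frame(source = character(0), target = character(0),
                      score = numeric(0), decision = character(0),
                      d_H1 = numeric(0), d_H0 = numeric(0)))
  do.call(rbind, lapply(x$results, function(r)
    data.frame(source = r$x_name, target = r$y_name, score = r$score,
               decision = r$decision, d_H1 = r$d_H1, d_H0 = r$d_H0,
               stringsAsFactors = FALSE)))
}

#' @export
print.cdd_network <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Causal network: %d nodes, %d evaluated pairs, %d accepted edges\n",
              length(x$variable_names), nrow(df),
              sum(df$decision == "H1")))
  invisible(x)
}

#' Evaluate an inferred network against a gold standard
#'
#' AUROC is computed from the continuous scores by the rank-sum
#' (pairwise comparison) definition with ties counted half; AUPR by
#' step-wise precision-recall summation over the score ranking. The
#' confusion counts use the binary H0/H1 decisions (H1 = predicted edge):
#' the method decides edge presence directly, without a score threshold.
#' Ordered pairs absent from the gold edge set count as negatives.
#'
#' @param network a \code{cdd_network}, or a data.frame with columns
#'   \code{source}, \code{target}, \code{score}, \code{decision}.
#' @param gold a \code{cdd_gold} over the same node universe.
#' @return a \code{cdd_evaluation}: list with \code{auc}, \code{aupr},
#'   counts \code{true_positive_edges}, \code{false_positive_edges},
#'   \code{false_negative_edges}, \code{true_negative_pairs}, and
#'   \code{n_pairs}.
#' @export
evaluate_network <- function(network, gold) {
  stopifnot(inherits(gold, "cdd_gold"))
  df <- if (inherits(network, "cdd_network")) as.data.frame(network)
        else as.data.frame(network)
  required <- c("source", "target", "score", "decision")
  if (!all(required %in% names(df)))
    stop("network table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(c(df$source, df$target)), gold$variable_names)
  if (length(unknown))
    stop("network contains nodes absent from the gold standard: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pos_keys <- paste(gold$edges[, "source"], gold$edges[, "target"],
                    sep = "\r")
  labels <- paste(df$source, df$target, sep = "\r") %in% pos_keys
  scores <- df$score
  n_pos <- sum(labels); n_neg <- sum(!labels)

  auc <- NA_real_
  if (n_pos == 0L || n_neg == 0L) {
    cdd_log("warning",
            "gold standard yields %d positives / %d negatives; AUC undefined",
            n_pos, n_neg)
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  aupr <- if (n_pos == 0L) NA_real_ else aupr_step(scores, labels)

  pred <- df$decision == "H1"
  structure(list(
    auc = auc, aupr = aupr,
    true_positive_edges = sum(pred & labels),
    false_positive_edges = sum(pred & !labels),
    false_negative_edges = sum(!pred & labels),
    true_negative_pairs = sum(!pred & !labels),
    n_pairs = nrow(df)),
    class = "cdd_evaluation")
}

# Step-wise precision-recall summation: walk the ranking by decreasing
# score (ties processed together) and accumulate precision * delta-recall.
aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n_pos <- sum(l)
  tp <- 0; fp <- 0; area <- 0; prev_recall <- 0
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    tp <- tp + sum(l[i:j]); fp <- fp + sum(!l[i:j])
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
    i <- j + 1L
  }
  area
}

#' @export
print.cdd_evaluation <- function(x, ...) {
  cat(sprintf("AUC  %.4f\nAUPR %.4f\n",
              x$auc, x$aupr))
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (of %d ordered pairs)\n",
              x$true_positive_edges, x$false_positive_edges,
              x$false_negative_edges, x$true_negative_pairs, x$n_pairs))
  invisible(x)
}
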