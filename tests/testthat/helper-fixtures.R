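# Shared test helpers: small in-code fixtures and independent oracles.

# A light configuration for unit tests where only mechanics are checked,
# not statistical power.
quick_config <- function(...) {
  cdd_config(utils::modifyList(
    list(timesteps = 20L, epochs = 50L, draws = 5L, seed = 7L),
    list(...)))
}

tiny_matrix <- function(n = 30L, seed = 3L) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  y <- 0.8 * x + 0.3 * z + 0.3 * rnorm(n)
  m <- cbind(x = x, z = z, y = y)
  scale(m)[, ]  # standardized, keep names
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent AUC oracle: explicit enumeration over all (positive,
# negative) score pairs, ties counted half.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Independent AUPR oracle: walk the ranking one item at a time and sum
# precision * delta-recall (assumes distinct scores).
aupr_stepsum <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  tp <- 0; fp <- 0; area <- 0; prev <- 0
  for (i in seq_along(l)) {
    if (l[i]) tp <- tp + 1 else fp <- fp + 1
    rec <- tp / sum(labels)
    prec <- tp / (tp + fp)
    area <- area + (rec - prev) * prec
    prev <- rec
  }
  area
}

# Independent biased-HSIC oracle: literal tr(K H L H) / n^2 with the
# centering matrix H = I - J/n.
hsic_definitional <- function(a, b, sigma2_a, sigma2_b) {
  n <- length(a)
  K <- exp(-outer(a, a, "-")^2 / (2 * sigma2_a))
  L <- exp(-outer(b, b, "-")^2 / (2 * sigma2_b))
  H <- diag(n) - matrix(1 / n, n, n)
  sum(diag(K %*% H %*% L %*% H)) / n^2
}

median_bw <- function(v) {
  d2 <- outer(v, v, "-")^2
  pos <- d2[upper.tri(d2)]
  pos <- pos[pos > 0]
  if (length(pos)) stats::median(pos) else 1
}
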