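#' @keywords internal
"_PACKAGE"

# Logging -----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set the logging verbosity
#'
#' Messages are written to standard error with a timestamp. The default
#' level is \code{"info"}.
#'
#' @param level one of \code{"debug"}, \code{"info"}, \code{"warning"},
#'   \code{"error"}.
#' @return the previous level, invisibly.
#' @export
cdd_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- getOption("cdd.log_level", "info")
  options(cdd.log_level = level)
  invisible(old)
}

cdd_log <- function(level, fmt, ...) {
  current <- getOption("cdd.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[current]]) return(invisible(NULL))
  msg <- sprintf(fmt, ...)
  cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              toupper(level), msg), file = stderr())
  invisible(NULL)
}

# Seeded evaluation --------------------------------------------------------

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}

# Standardization -----------------------------------------------------------

# Column means/sds from a training matrix; sd floored so constant columns
# do not blow up (a warning is the caller's job).
standardize_stats <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mean = mu, sd = sd)
}

apply_standardize <- function(m, stats) {
  sweep(sweep(m, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
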