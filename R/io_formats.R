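# Readers/writers for the benchmark dialects: expression matrices as
# tab-separated files with a header row of variable names and one row per
# sample, and gold-standard edge lists as `source<TAB>target<TAB>{0,1}`.

#' Load an expression matrix
#'
#' Reads a tab-separated file whose first row names the variables and whose
#' remaining rows are numeric samples. Any time-series structure in the file
#' is deliberately ignored: rows are treated as exchangeable samples, as the
#' edge test assumes cross-sectional data.
#'
#' @param path path to a TSV file.
#' @return an object of class \code{cdd_expression}: a list with
#'   \code{values} (numeric matrix, samples x variables),
#'   \code{variable_names}, and \code{sample_count}.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty expression file: ", path, call. = FALSE)
  header <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (anyDuplicated(header))
    stop("duplicate variable names in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(header))) stop("empty variable name in header", call. = FALSE)
  p <- length(header)
  n <- length(lines) - 1L
  values <- matrix(NA_real_, nrow = n, ncol = p,
                   dimnames = list(NULL, header))
  for (i in seq_len(n)) {
    fields <- trimws(strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != p)
      stop(sprintf("ragged row %d: expected %d fields, got %d",
                   i, p, length(fields)), call. = FALSE)
    suppressWarnings(num <- as.numeric(fields))
    bad <- which(!is.finite(num))
    if (length(bad))
      stop(sprintf("non-finite or malformed value at row %d, column %s ('%s')",
                   i, header[bad[1L]], fields[bad[1L]]), call. = FALSE)
    values[i, ] <- num
  }
  new_expression(values, header)
}

new_expression <- function(values, variable_names) {
  stopifnot(is.matrix(values), ncol(values) == length(variable_names))
  colnames(values) <- variable_names
  structure(list(values = values,
                 variable_names = variable_names,
                 sample_count = nrow(values)),
            class = "cdd_expression")
}

#' Write an expression matrix
#'
#' Inverse of [load_expression()]; the round trip preserves values to
#' floating precision.
#'
#' @param expression a \code{cdd_expression}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expression, path) {
  stopifnot(inherits(expression, "cdd_expression"))
  rows <- apply(expression$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(expression$variable_names, collapse = "\t"), rows), path)
  invisible(path)
}

#' @export
print.cdd_expression <- function(x, ...) {
  cat(sprintf("Expression matrix: %d samples x %d variables\n",
              x$sample_count, length(x$variable_names)))
  cat("Variables:", paste(utils::head(x$variable_names, 8L), collapse = ", "),
      if (length(x$variable_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Load a gold-standard edge list
#'
#' Each line is \code{source<TAB>target<TAB>label}, label 1 for a confirmed
#' edge and 0 for a confirmed non-edge (the DREAM convention). Label-0 lines
#' are recorded as explicit negatives; pairs absent from the file are also
#' treated as negatives at evaluation time.
#'
#' @param path path to a TSV edge list.
#' @param variable_names the node universe; edge endpoints must belong to it.
#' @return an object of class \code{cdd_gold}: list with \code{edges}
#'   (two-column character matrix of directed edges), \code{negatives}
#'   (explicit label-0 pairs), \code{variable_names}.
#' @export
load_gold_standard <- function(path, variable_names) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pos <- character(0); neg <- character(0)
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields", i),
           call. = FALSE)
    src <- fields[1L]; tgt <- fields[2L]; lab <- fields[3L]
    if (!lab %in% c("0", "1"))
      stop(sprintf("line %d: label must be 0 or 1, got '%s'", i, lab),
           call. = FALSE)
    if (!src %in% variable_names || !tgt %in% variable_names)
      stop(sprintf("line %d: unknown node name '%s'", i,
                   if (src %in% variable_names) tgt else src), call. = FALSE)
    if (src == tgt)
      stop(sprintf("line %d: self-edge %s -> %s not allowed", i, src, tgt),
           call. = FALSE)
    key <- paste(src, tgt, sep = "\r")
    if (lab == "1") pos <- c(pos, key) else neg <- c(neg, key)
  }
  pos <- unique(pos); neg <- unique(neg)
  split_keys <- function(k) {
    if (!length(k)) return(matrix(character(0), ncol = 2L,
                                  dimnames = list(NULL, c("source", "target"))))
    m <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    colnames(m) <- c("source", "target")
    m
  }
  structure(list(edges = split_keys(pos), negatives = split_keys(neg),
                 variable_names = variable_names),
            class = "cdd_gold")
}

#' @export
print.cdd_gold <- function(x, ...) {
  cat(sprintf("Gold standard: %d edges, %d explicit negatives, %d nodes\n",
              nrow(x$edges), nrow(x$negatives), length(x$variable_names)))
  invisible(x)
}

#' Write a network's edge table
#'
#' One row per evaluated ordered pair, ordered source-major then target by
#' the input variable order, so identical networks serialize byte-identically.
#'
#' @param network a \code{cdd_network} from [infer_network()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "cdd_network"))
  df <- as.data.frame(network)
  header <- "source\ttarget\tscore\tdecision\td_H1\td_H0"
  rows <- character(nrow(df))
  if (nrow(df)) {
    rows <- sprintf("%s\t%s\t%.10g\t%s\t%.10g\t%.10g",
                    df$source, df$target, df$score, df$decision,
                    df$d_H1, df$d_H0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a configuration file
#'
#' Accepts YAML or simple `key: value` / `key = value` lines. Keys mirror
#' the command-line flags; flags override config values.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.list(cfg)) return(cfg)
  # fall back to key = value lines
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[:=]", perl = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    val <- trimws(paste(kv[-1L], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(kv[1L])]] <- if (!is.na(num)) num else val
  }
  out
}
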