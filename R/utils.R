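# Internal helpers shared across modules.

# Deterministic 31-bit child seeds: stream `k` of master `seed`. Keeps every
# derived seed in [0, 2^31 - 2] so set.seed() is safe on 32-bit integers, and
# changing the number of streams never reshuffles earlier streams.
child_seed <- function(seed, k) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + k) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("netfactor_input_error", "error")))
}

stop_solver <- function(...) {
  stop(errorCondition(paste0(...), class = c("netfactor_solver_error", "error")))
}

# Validate an expression matrix: numeric, named, no NA, unique gene ids.
check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_input("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_input("expression matrix needs gene rownames and sample colnames")
  if (ncol(expr) < 2) stop_input("expression matrix needs >= 2 samples")
  if (anyDuplicated(rownames(expr)))
    stop_input("duplicated gene ids: ",
               paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                     collapse = ", "))
  if (anyNA(expr)) {
    idx <- which(is.na(expr), arr.ind = TRUE)[1, ]
    stop_input("missing value in expression matrix at gene '",
               rownames(expr)[idx[1]], "', sample '", colnames(expr)[idx[2]], "'")
  }
  invisible(expr)
}

# Labels: named vector mapping sample id -> "case"/"control", or unnamed and
# aligned with the matrix columns. Returns a character vector aligned to
# colnames(expr).
check_labels <- function(labels, expr) {
  lab <- as.character(labels)
  if (!is.null(names(labels))) {
    missing <- setdiff(names(labels), colnames(expr))
    if (length(missing))
      stop_input("labeled samples absent from expression matrix: ",
                 paste(missing, collapse = ", "))
    lab <- as.character(labels)[match(colnames(expr), names(labels))]
  } else if (length(labels) != ncol(expr)) {
    stop_input("unnamed labels must have one entry per sample")
  }
  if (anyNA(lab)) stop_input("every sample needs a class label")
  bad <- setdiff(unique(lab), c("case", "control"))
  if (length(bad))
    stop_input("labels must be 'case'/'control', got: ", paste(bad, collapse = ", "))
  names(lab) <- colnames(expr)
  lab
}

# Shared hypergeometric upper-tail kernel: P(X >= k) drawing n from an urn
# with K successes out of N. All enrichment/overlap tests in the package
# reduce to this one call.
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Fixed-format float used in every TSV writer (6 significant digits).
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(signif(v, 6), trim = TRUE)
  }, character(1))
}
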