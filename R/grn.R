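# Gene regulatory network container and ARACNE-style consensus inference.

#' Construct a gene regulatory network object
#'
#' A GRN is a set of directed TF -> target edges carrying a mutual
#' information weight, a bootstrap support fraction and a regulation mode
#' (-1 repression, +1 activation, 0 undetermined, NA not yet assigned).
#'
#' @param edges data frame with columns `tf`, `target` and optionally `mi`,
#'   `support`, `mode`. Missing `mi`/`support` default to 1, missing `mode`
#'   to NA (assign with [assign_modes()]).
#' @param tfs TF universe; defaults to the TFs appearing in `edges`.
#' @return object of class `netfactor_grn` with elements `tfs`, `genes`
#'   (all node ids) and `edges`.
#' @export
grn <- function(edges, tfs = unique(edges$tf)) {
  stopifnot(is.data.frame(edges), all(c("tf", "target") %in% names(edges)))
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  if (any(edges$tf == edges$target)) stop_input("self-regulation edges are not allowed")
  if (anyDuplicated(edges[c("tf", "target")]))
    stop_input("duplicate (tf, target) pairs")
  if (!all(edges$tf %in% tfs)) stop_input("every edge tf must be in the TF set")
  edges$mi <- if (is.null(edges$mi)) rep(1, nrow(edges)) else as.numeric(edges$mi)
  if (any(edges$mi < 0)) stop_input("mi must be >= 0")
  edges$support <- if (is.null(edges$support)) rep(1, nrow(edges)) else as.numeric(edges$support)
  edges$mode <- if (is.null(edges$mode)) rep(NA_integer_, nrow(edges)) else as.integer(edges$mode)
  edges <- edges[order(edges$tf, edges$target, method = "radix"),
                 c("tf", "target", "mi", "support", "mode"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(tfs = sort(unique(as.character(tfs)), method = "radix"),
                 genes = sort(unique(c(edges$tf, edges$target, as.character(tfs))), method = "radix"),
                 edges = edges),
            class = "netfactor_grn")
}

#' @export
print.netfactor_grn <- function(x, ...) {
  cat("Gene regulatory network:", nrow(x$edges), "edges,",
      length(unique(x$edges$tf)), "TFs with targets,",
      length(x$genes), "nodes\n")
  invisible(x)
}

#' Extract regulons from a network
#'
#' @param x a `netfactor_grn`.
#' @return named list (one element per TF with at least one target) of data
#'   frames with columns `target`, `mode`.
#' @export
regulons <- function(x) {
  stopifnot(inherits(x, "netfactor_grn"))
  f <- factor(x$edges$tf, levels = unique(x$edges$tf)) # edges are radix-sorted
  lapply(split(x$edges[c("target", "mode")], f),
         function(d) { rownames(d) <- NULL; d })
}

# One ARACNE-style pass on a (possibly resampled) expression matrix:
# permutation-calibrated MI threshold, MI map, DPI. Returns directed edges.
aracne_pass <- function(expr, tfs, n_bins, dpi_tolerance,
                        null_shuffles, null_quantile) {
  genes <- rownames(expr)
  G <- length(genes); n <- ncol(expr)
  B <- bin_rows(expr, n_bins)
  # null MI from randomly paired (overwhelmingly unrelated) genes of the
  # same matrix: computed within the resample, so it carries the same
  # duplicated-sample inflation as the real pairs
  null_mi <- vapply(seq_len(null_shuffles), function(s) {
    ij <- sample.int(G, 2)
    mi_bins_single(B[ij[1], ], B[ij[2], ], n_bins)
  }, numeric(1))
  thr <- as.numeric(quantile(null_mi, null_quantile, type = 1, names = FALSE))
  # gene-gene edges are inert for the surviving TF -> target set (the DPI
  # exception always removes them), so the consensus path skips them
  mi_map <- build_mi_matrix(expr, tfs, n_bins = n_bins, mi_threshold = thr,
                            gene_pairs = FALSE)
  apply_dpi(mi_map, tfs, tolerance = dpi_tolerance)
}

#' Bootstrap consensus gene regulatory network (ARACNE-style)
#'
#' Infers a GRN by resampling samples with replacement `n_boot` times, and
#' on each bootstrap: calibrating an MI significance threshold from
#' `null_shuffles` randomly paired gene profiles (keeping MI above the
#' `null_quantile` of that null), building the MI map restricted to
#' transcriptional pairs, and pruning indirect edges with the DPI. The
#' consensus keeps edges whose occurrence count across bootstraps is
#' significant under a binomial null with success probability equal to the
#' observed mean edge frequency, Benjamini-Hochberg corrected at
#' `mi_threshold_p` (the filter is skipped for `n_boot = 1`, where the
#' consensus is the single bootstrap network). Edge MI is the mean over the
#' bootstraps containing the edge; support is the occurrence fraction.
#'
#' @param expr numeric matrix, genes x samples (>= 8 samples).
#' @param tf_list candidate TF ids.
#' @param n_boot number of bootstraps (default 100).
#' @param mi_threshold_p BH-adjusted significance level for consensus edge
#'   retention (default 0.05).
#' @param n_bins MI bin count (default from sample size).
#' @param dpi_tolerance DPI tolerance (default 0).
#' @param null_shuffles,null_quantile per-bootstrap MI null calibration:
#'   number of shuffled gene pairs and the null quantile used as threshold.
#' @param seed integer seed; each bootstrap draws from its own child seed so
#'   results are reproducible and earlier bootstraps do not change when
#'   `n_boot` grows.
#' @return a [grn()] object (modes unassigned; see [assign_modes()]).
#' @export
bootstrap_consensus <- function(expr, tf_list, n_boot = 100,
                                mi_threshold_p = 0.05,
                                n_bins = default_bins(ncol(expr)),
                                dpi_tolerance = 0,
                                null_shuffles = 100, null_quantile = 0.95,
                                seed = 1) {
  check_expression(expr)
  if (n_boot < 1) stop_input("n_boot must be >= 1")
  if (ncol(expr) < 8) stop_input("need >= 8 samples for bootstrap inference")
  genes <- sort(rownames(expr), method = "radix")
  expr <- expr[genes, , drop = FALSE]
  tfs <- sort(intersect(tf_list, genes), method = "radix")
  if (!length(tfs)) stop_input("no TF in tf_list is present in the expression matrix")
  n <- ncol(expr); G <- length(genes)

  keys <- vector("list", n_boot)
  mis <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    ed <- aracne_pass(expr[, idx, drop = FALSE], tfs, n_bins, dpi_tolerance,
                      null_shuffles, null_quantile)
    keys[[b]] <- (match(ed$tf, genes) - 1) * G + match(ed$target, genes)
    mis[[b]] <- ed$mi
  }
  key <- unlist(keys); mi <- unlist(mis)
  if (!length(key)) {
    return(grn(data.frame(tf = character(0), target = character(0),
                          mi = numeric(0), support = numeric(0)), tfs = tfs))
  }
  count <- vapply(split(key, key), length, integer(1))
  mi_mean <- vapply(split(mi, key), mean, numeric(1))
  ukey <- as.numeric(names(count))

  keep <- rep(TRUE, length(ukey))
  if (n_boot > 1) {
    p0 <- mean(count) / n_boot # observed mean edge frequency
    if (p0 < 1) {
      pval <- pbinom(count - 1, n_boot, p0, lower.tail = FALSE)
      keep <- p.adjust(pval, method = "BH") <= mi_threshold_p
    }
  }
  tf_id <- genes[(ukey[keep] - 1) %/% G + 1]
  tg_id <- genes[(ukey[keep] - 1) %% G + 1]
  grn(data.frame(tf = tf_id, target = tg_id, mi = mi_mean[keep],
                 support = count[keep] / n_boot, stringsAsFactors = FALSE),
      tfs = tfs)
}

#' Assign regulation modes from the expression data
#'
#' The mode (direction) of each edge is the sign of the Spearman correlation
#' between TF and target expression across all samples -- the convention
#' used by regulon-activity methods, since MI itself is unsigned. A
#' correlation of exactly 0 (or an undefined one on a constant profile)
#' yields mode 0 with a warning; mode-0 edges stay in the network but are
#' skipped by the activity score.
#'
#' @param expr numeric matrix, genes x samples.
#' @param network a [grn()] object whose edge endpoints all appear in `expr`.
#' @return the network with the `mode` column filled in.
#' @export
assign_modes <- function(expr, network) {
  stopifnot(inherits(network, "netfactor_grn"))
  check_expression(expr)
  nodes <- unique(c(network$edges$tf, network$edges$target))
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing))
    stop_input("edge endpoints absent from expression matrix: ",
               paste(missing, collapse = ", "))
  if (!nrow(network$edges)) return(network)
  rk <- t(apply(expr[nodes, , drop = FALSE], 1, rank))
  rk <- rk - rowMeans(rk)
  den <- sqrt(rowSums(rk^2))
  i <- match(network$edges$tf, nodes)
  j <- match(network$edges$target, nodes)
  num <- rowSums(rk[i, , drop = FALSE] * rk[j, , drop = FALSE])
  rho <- ifelse(den[i] * den[j] > 0, num / (den[i] * den[j]), 0)
  mode <- as.integer(sign(round(rho, 12)))
  if (any(mode == 0L))
    warning(sum(mode == 0L), " edge(s) with zero rank correlation: mode set to 0")
  network$edges$mode <- mode
  network
}

#' Read / write a network edge list (TSV)
#'
#' The edge-list format is a UTF-8 TSV with header
#' `tf<TAB>target<TAB>mi<TAB>support<TAB>mode`. Networks produced by other
#' inference tools may omit `support` and/or `mode`; missing support
#' defaults to 1 and missing mode to NA (recompute with [assign_modes()]).
#'
#' @param path file path.
#' @return `read_network`: a [grn()] object.
#' @export
read_network <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("tf", "target") %in% names(d)))
    stop_input("network file needs 'tf' and 'target' columns: ", path)
  grn(d)
}

#' @rdname read_network
#' @param network a [grn()] object to serialize.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "netfactor_grn"))
  d <- network$edges
  d$mi <- fmt_num(d$mi)
  d$support <- fmt_num(d$support)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
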