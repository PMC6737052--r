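#' Plug-in mutual information with equal-frequency binning
#'
#' Estimates the mutual information (in nats) between two numeric vectors
#' from the `n_bins` x `n_bins` contingency table obtained by rank-based
#' equal-frequency discretization of each vector. Ties are broken by
#' position (stable order), so the estimate is deterministic, including on
#' bootstrap resamples containing exact duplicates. Rank binning makes the
#' estimate invariant to monotone transforms of the expression units.
#'
#' A constant vector carries no information; its MI is defined as 0 (with a
#' warning) rather than letting arbitrary tie-splitting manufacture
#' dependence.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of equal-frequency bins (>= 2); default
#'   `max(2, floor(sqrt(length(x) / 5)))`, which keeps roughly >= 5
#'   observations per marginal bin.
#' @return mutual information in nats (non-negative scalar).
#' @examples
#' estimate_mi(c(1, 2, 3, 4), c(1, 3, 2, 4), n_bins = 2)  # 0: independent bins
#' estimate_mi(1:8, 1:8, n_bins = 2)                      # log(2)
#' @export
estimate_mi <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_input("missing values are not allowed")
  n <- length(x)
  if (n_bins < 2) stop_input("n_bins must be >= 2")
  if (n < n_bins) stop_input("need at least n_bins observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: MI defined as 0")
    return(0)
  }
  B <- bin_rows(rbind(x, y), as.integer(n_bins))
  mi_bins_single(B[1, ], B[2, ], as.integer(n_bins))
}

#' @rdname estimate_mi
#' @param n_samples sample count from which to derive the default bin number.
#' @export
default_bins <- function(n_samples) max(2L, as.integer(floor(sqrt(n_samples / 5))))

#' Pairwise mutual information map for network inference
#'
#' Computes MI for every TF-involving gene pair (TF-TF and TF-gene), and for
#' the gene-gene pairs that can close a 3-clique with two TF edges above
#' `mi_threshold` (the only non-transcriptional edges the DPI step ever
#' needs to inspect). Pairs with MI at or below `mi_threshold` are omitted
#' from the result.
#'
#' @param expr numeric matrix, genes x samples, with gene rownames.
#' @param tf_list character vector of TF gene ids; ids absent from `expr`
#'   are dropped with a warning.
#' @param n_bins equal-frequency bin count (default from sample size).
#' @param mi_threshold retain pairs with MI strictly above this value
#'   (default `-Inf`: all computed pairs are returned).
#' @param gene_pairs compute the triangle-closing gene-gene pairs (default
#'   TRUE). The DPI exception rule makes non-TF/non-TF edges inert for the
#'   surviving TF -> target edge set (they are always the removal victim in
#'   any triangle containing them), so the bootstrap-consensus path disables
#'   them for speed; the resulting networks are identical.
#' @return data frame with columns `node1`, `node2`, `mi` (undirected pairs,
#'   `node1 < node2` lexicographically), ordered deterministically.
#' @export
build_mi_matrix <- function(expr, tf_list, n_bins = default_bins(ncol(expr)),
                            mi_threshold = -Inf, gene_pairs = TRUE) {
  check_expression(expr)
  genes <- sort(rownames(expr), method = "radix")
  expr <- expr[genes, , drop = FALSE]
  missing_tfs <- setdiff(tf_list, genes)
  if (length(missing_tfs))
    warning("TFs absent from expression matrix dropped: ",
            paste(missing_tfs, collapse = ", "))
  tfs <- sort(intersect(tf_list, genes), method = "radix")
  if (!length(tfs)) stop_input("no TF in tf_list is present in the expression matrix")

  n_bins <- as.integer(n_bins)
  B <- bin_rows(expr, n_bins)
  tf_idx <- match(tfs, genes)
  is_tf <- seq_along(genes) %in% tf_idx

  # TF-involving pairs
  pair_i <- integer(0); pair_j <- integer(0)
  if (length(tf_idx) >= 2) {
    tt <- combn(tf_idx, 2)
    pair_i <- c(pair_i, tt[1, ]); pair_j <- c(pair_j, tt[2, ])
  }
  non_tf <- setdiff(seq_along(genes), tf_idx)
  if (length(non_tf)) {
    pair_i <- c(pair_i, rep(tf_idx, each = length(non_tf)))
    pair_j <- c(pair_j, rep(non_tf, times = length(tf_idx)))
  }
  mi <- mi_pairs_cpp(B, pair_i, pair_j, n_bins)
  keep <- mi > mi_threshold
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]; mi <- mi[keep]

  # gene-gene pairs closing a triangle with two retained TF edges
  if (gene_pairs && length(non_tf)) {
    nbrs <- split(ifelse(is_tf[pair_i], pair_j, pair_i),
                  ifelse(is_tf[pair_i], pair_i, pair_j))
    gg_i <- integer(0); gg_j <- integer(0)
    for (v in nbrs) {
      v <- sort(v[!is_tf[v]])
      L <- length(v)
      if (L >= 2) {
        idx <- seq_len(L - 1)
        gg_i <- c(gg_i, v[rep.int(idx, rev(idx))])
        gg_j <- c(gg_j, v[sequence(rev(idx), from = idx + 1L)])
      }
    }
    if (length(gg_i)) {
      key <- (gg_i - 1) * length(genes) + gg_j
      dup <- duplicated(key)
      gg_i <- gg_i[!dup]; gg_j <- gg_j[!dup]
      mi_gg <- mi_pairs_cpp(B, gg_i, gg_j, n_bins)
      keep <- mi_gg > mi_threshold
      pair_i <- c(pair_i, gg_i[keep]); pair_j <- c(pair_j, gg_j[keep])
      mi <- c(mi, mi_gg[keep])
    }
  }

  lo <- pmin(pair_i, pair_j); hi <- pmax(pair_i, pair_j)
  # index order equals lexicographic id order (genes are sorted)
  ord <- order((lo - 1) * length(genes) + hi)
  out <- data.frame(node1 = genes[lo][ord], node2 = genes[hi][ord],
                    mi = mi[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tfs") <- tfs
  out
}

#' Data processing inequality (DPI) pruning of an MI map
#'
#' For every 3-clique of the MI graph the minimum-MI edge is removed as a
#' likely indirect interaction, with one exception: when removing it would
#' retain a non-TF/non-TF edge -- which is not a transcriptional
#' interaction -- that edge is removed instead. An edge survives only if no
#' clique removed it; removals are decided on the input graph. A tolerance
#' `t > 0` keeps the minimum edge of a clique when
#' `min_mi >= (1 - t) * second_mi`. Exact MI ties at tolerance 0 are broken
#' by removing the edge with the lexicographically smallest (tf, target)
#' pair, so pruning is deterministic.
#'
#' @param mi_map data frame with columns `node1`, `node2`, `mi` as produced
#'   by [build_mi_matrix()].
#' @param tf_list character vector of TF ids.
#' @param tolerance DPI tolerance fraction in `[0, 1)`, default 0.
#' @return data frame of directed surviving transcriptional edges with
#'   columns `tf`, `target`, `mi`. A surviving TF-TF edge contributes both
#'   directions; non-transcriptional edges never appear in the output.
#' @export
apply_dpi <- function(mi_map, tf_list, tolerance = 0) {
  if (!nrow(mi_map)) {
    return(data.frame(tf = character(0), target = character(0), mi = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (tolerance < 0 || tolerance >= 1) stop_input("tolerance must be in [0, 1)")
  nodes <- sort(unique(c(mi_map$node1, mi_map$node2)), method = "radix")
  is_tf <- nodes %in% tf_list
  ei <- match(mi_map$node1, nodes)
  ej <- match(mi_map$node2, nodes)
  if (any(ei == ej)) stop_input("self-edges are not allowed")
  keep <- dpi_keep_cpp(length(nodes), is_tf, ei, ej, mi_map$mi, tolerance)
  ei <- ei[keep]; ej <- ej[keep]; mi <- mi_map$mi[keep]

  tf_i <- is_tf[ei]; tf_j <- is_tf[ej]
  both <- tf_i & tf_j
  one_i <- tf_i & !tf_j
  one_j <- tf_j & !tf_i
  tf_ix <- c(ei[one_i], ej[one_j], ei[both], ej[both])
  tg_ix <- c(ej[one_i], ei[one_j], ej[both], ei[both])
  mi_out <- c(mi[one_i], mi[one_j], mi[both], mi[both])
  ord <- order((tf_ix - 1) * length(nodes) + tg_ix) # nodes sorted: name order
  out <- data.frame(tf = nodes[tf_ix][ord], target = nodes[tg_ix][ord],
                    mi = mi_out[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
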