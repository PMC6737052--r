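# Robustness comparisons: edge overlap between networks, correlation of
# activity scores, overlap of top-k ranked regulator lists. All three
# reduce to the same hypergeometric kernel as fisher_overlap().

#' Edge-overlap test between two networks
#'
#' One-sided Fisher's exact test (greater) of the overlap between the
#' directed edge sets of two GRNs. The universe of possible edges is every
#' (TF, target) ordered pair over the union (default) or intersection of
#' the two node sets, minus self-pairs.
#'
#' @param net1,net2 [grn()] objects.
#' @param edge_universe `"union"` (default) or `"intersection"`.
#' @return list with `shared`, `n1`, `n2`, `n_universe`, `p`.
#' @export
edge_overlap_test <- function(net1, net2, edge_universe = c("union", "intersection")) {
  stopifnot(inherits(net1, "netfactor_grn"), inherits(net2, "netfactor_grn"))
  edge_universe <- match.arg(edge_universe)
  if (!nrow(net1$edges) || !nrow(net2$edges)) stop_input("empty network")
  comb <- if (edge_universe == "union") union else intersect
  tf_u <- comb(net1$tfs, net2$tfs)
  tg_u <- comb(unique(net1$edges$target), unique(net2$edges$target))
  n_pairs <- length(tf_u) * length(tg_u) - length(intersect(tf_u, tg_u))
  e1 <- paste(net1$edges$tf, net1$edges$target, sep = "\r")
  e2 <- paste(net2$edges$tf, net2$edges$target, sep = "\r")
  if (edge_universe == "intersection") {
    keep1 <- net1$edges$tf %in% tf_u & net1$edges$target %in% tg_u
    keep2 <- net2$edges$tf %in% tf_u & net2$edges$target %in% tg_u
    e1 <- e1[keep1]; e2 <- e2[keep2]
  }
  shared <- length(intersect(e1, e2))
  list(shared = shared, n1 = length(e1), n2 = length(e2),
       n_universe = n_pairs,
       p = hyper_upper_tail(shared, length(e1), length(e2), n_pairs))
}

#' Correlation of TF activity scores from two analyses
#'
#' Pearson correlation (with the two-sided t-based p-value) of the NES
#' vectors of the TFs scored in both activity tables.
#'
#' @param act1,act2 activity data frames (from [tf_activity()]).
#' @return list with `r`, `p`, `n` (TFs compared).
#' @export
activity_correlation <- function(act1, act2) {
  m <- merge(act1[c("tf", "nes")], act2[c("tf", "nes")], by = "tf")
  m <- m[!is.na(m$nes.x) & !is.na(m$nes.y), , drop = FALSE]
  if (nrow(m) < 3) stop_input("need >= 3 TFs scored in both analyses")
  ct <- cor.test(m$nes.x, m$nes.y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Overlap test between the top-k of two ranked regulator lists
#'
#' Hypergeometric (one-sided, greater) test of the overlap between the
#' first `k` entries of two ranked TF lists drawn from a common universe of
#' `n_universe` TFs.
#'
#' @param list1,list2 character vectors of TF ids, best first, without
#'   duplicates.
#' @param k prefix length compared (default 10).
#' @param n_universe size of the common TF universe. If the two lists
#'   declare different universes, supply the value explicitly.
#' @return list with `overlap`, `k`, `n_universe`, `p`.
#' @export
topk_overlap_test <- function(list1, list2, k = 10,
                              n_universe = length(union(list1, list2))) {
  if (anyDuplicated(list1) || anyDuplicated(list2))
    stop_input("ranked lists must not contain duplicates")
  if (k > min(length(list1), length(list2)))
    stop_input("k exceeds a list length")
  if (n_universe < k) stop_input("universe smaller than k")
  ov <- length(intersect(list1[seq_len(k)], list2[seq_len(k)]))
  list(overlap = ov, k = k, n_universe = n_universe,
       p = hyper_upper_tail(ov, k, k, n_universe))
}
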