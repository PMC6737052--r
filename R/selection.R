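# Coverage matrix, L1-relaxed set cover, ranking, dual-FDR filter, greedy
# baseline and coverage curves.

#' Build the TF x biomarker-gene coverage matrix
#'
#' Entry `A[i, j] = (1 - fdr_viper_i) * (1 - fdr_biomarker_i)` when gene `j`
#' is a target of TF `i` in the network, and 0 otherwise -- the joint
#' likelihood that the TF is disease-active and regulates the biomarker.
#' Columns are restricted to biomarker genes with at least one positive
#' entry; the remaining ("uncovered") biomarker genes are recorded in the
#' `uncovered` attribute. TFs with NA activity are dropped with a warning;
#' TFs targeting no biomarker gene keep an all-zero row (their weight will
#' be 0).
#'
#' @param network a [grn()] object.
#' @param activity data frame from [tf_activity()].
#' @param enrichment data frame from [enrich_all()].
#' @param biomarker character vector of biomarker gene ids.
#' @return numeric matrix (TFs x coverable biomarker genes) with attribute
#'   `uncovered`.
#' @export
build_coverage_matrix <- function(network, activity, enrichment, biomarker) {
  stopifnot(inherits(network, "netfactor_grn"))
  regs <- regulons(network)
  tfs <- names(regs)
  miss_a <- setdiff(tfs, activity$tf)
  miss_e <- setdiff(tfs, enrichment$tf)
  if (length(miss_a) || length(miss_e))
    stop_input("activity/enrichment must cover every network TF; missing: ",
               paste(unique(c(miss_a, miss_e)), collapse = ", "))
  fdr_v <- setNames(activity$fdr_viper, activity$tf)[tfs]
  fdr_b <- setNames(enrichment$fdr_biomarker, enrichment$tf)[tfs]
  drop <- is.na(fdr_v)
  if (any(drop)) {
    warning("dropping ", sum(drop), " TF(s) with NA activity: ",
            paste(tfs[drop], collapse = ", "))
    tfs <- tfs[!drop]
  }
  biomarker <- unique(as.character(biomarker))
  A <- matrix(0, length(tfs), length(biomarker),
              dimnames = list(tfs, biomarker))
  for (tf in tfs) {
    hit <- intersect(regs[[tf]]$target, biomarker)
    if (length(hit)) A[tf, hit] <- (1 - fdr_v[tf]) * (1 - fdr_b[tf])
  }
  coverable <- colSums(A > 0) > 0
  if (!any(coverable)) stop_input("no biomarker gene is coverable by the network")
  out <- A[, coverable, drop = FALSE]
  attr(out, "uncovered") <- sort(biomarker[!coverable], method = "radix")
  out
}

#' Solve the L1-relaxed weighted set cover
#'
#' The exact regulator-selection problem -- pick the fewest TFs such that
#' every coverable biomarker gene is covered with total likelihood at least
#' 1 -- is a binary program (minimize the L0 norm subject to `A'x >= 1`,
#' `x` binary) and intractable in general. Its L1 relaxation
#' `min sum(x) s.t. sum_i A[i, j] x_i >= 1 for every gene j, x >= 0`
#' is a linear program whose solution weights ("LASSO weights") rank the
#' TFs. The relaxation drops the binary upper bound, so weights above 1 are
#' legitimate (a TF with likelihood entries `a < 1` needs weight `1/a` to
#' cover a gene on its own).
#'
#' The optimal objective is unique but the solution vector need not be
#' (e.g. duplicated regulons). A second LP over the optimal face --
#' minimizing a fixed, rank-indexed perturbation objective subject to the
#' original constraints and `sum(x) <= objective` -- canonicalizes the
#' returned weights deterministically (earlier rows preferred).
#'
#' @param A coverage matrix from [build_coverage_matrix()] (TFs x genes;
#'   every column must have a positive entry).
#' @param feas_tol feasibility tolerance for the returned solution.
#' @return list with `weights` (named, >= 0), `objective` and `status`.
#' @export
solve_l1_cover <- function(A, feas_tol = 1e-6) {
  if (!is.matrix(A) || !nrow(A) || !ncol(A)) stop_input("A must be a non-empty matrix")
  if (any(colSums(A > 0) == 0))
    stop_input("every column of A needs a positive entry")
  t_n <- nrow(A); g_n <- ncol(A)
  Ag <- t(A) # genes x TFs: constraint rows
  r1 <- simplex_lp(rep(1, t_n), A_ge = Ag, b_ge = rep(1, g_n))
  if (r1$status != "optimal")
    stop_solver("LP solver failed: ", r1$status)
  v <- r1$value
  # canonicalization over the optimal face: minimize a rank-indexed
  # perturbation objective subject to optimality of the primary objective
  r2 <- simplex_lp(seq_len(t_n), A_ge = Ag, b_ge = rep(1, g_n),
                   A_le = matrix(1, 1, t_n), b_le = v * (1 + 1e-9) + 1e-12)
  x <- if (r2$status == "optimal") r2$x else r1$x
  x <- pmax(x, 0)
  resid <- min(Ag %*% x) # must cover every gene
  if (resid < 1 - feas_tol)
    stop_solver("LP solution infeasible: min coverage ", format(resid))
  list(weights = setNames(as.numeric(x), rownames(A)),
       objective = sum(x), status = "optimal")
}

#' Greedy coverage baseline
#'
#' Orders TFs by the raw number of biomarker genes they target in the
#' network (static counts -- deliberately ignoring redundancy among the
#' target sets, which is what the L1 program improves on), ties broken
#' lexicographically, and reports the cumulative number of distinct
#' biomarker genes covered along that order.
#'
#' @param network a [grn()] object.
#' @param biomarker character vector of biomarker gene ids.
#' @return list with `order` (TF ids), `counts` (per-TF biomarker target
#'   counts, in order) and `curve` (cumulative distinct coverage).
#' @export
greedy_cover <- function(network, biomarker) {
  stopifnot(inherits(network, "netfactor_grn"))
  biomarker <- unique(as.character(biomarker))
  regs <- regulons(network)
  hits <- lapply(regs, function(r) intersect(r$target, biomarker))
  counts <- vapply(hits, length, integer(1))
  if (!any(counts > 0)) stop_input("biomarker and network targets are disjoint")
  ord <- names(regs)[order(-counts, names(regs), method = "radix")]
  covered <- character(0)
  curve <- integer(length(ord))
  for (k in seq_along(ord)) {
    covered <- union(covered, hits[[ord[k]]])
    curve[k] <- length(covered)
  }
  list(order = ord, counts = as.integer(counts[ord]), curve = curve)
}

#' Rank TFs by set-cover weight
#'
#' Descending LP weight; ties broken by ascending
#' `fdr_viper * fdr_biomarker`, then lexicographically. Zero-weight TFs are
#' ranked last under the same secondary keys.
#'
#' @param weights named weight vector from [solve_l1_cover()].
#' @param activity data frame from [tf_activity()].
#' @param enrichment data frame from [enrich_all()].
#' @return data frame `tf`, `weight`, `rank` in rank order.
#' @export
rank_regulators <- function(weights, activity, enrichment) {
  tfs <- names(weights)
  fdr_v <- setNames(activity$fdr_viper, activity$tf)[tfs]
  fdr_b <- setNames(enrichment$fdr_biomarker, enrichment$tf)[tfs]
  key2 <- ifelse(is.na(fdr_v * fdr_b), Inf, fdr_v * fdr_b)
  ord <- order(-weights, key2, tfs, method = "radix")
  out <- data.frame(tf = tfs[ord], weight = as.numeric(weights[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Final significant regulator set (dual-FDR filter)
#'
#' The selected regulators are the positively weighted TFs that are both
#' significantly differentially active (`fdr_viper <= alpha`) and
#' significant regulators of the biomarker (`fdr_biomarker <= alpha`),
#' returned in rank order. An empty result is legitimate (e.g. no
#' disease-active regulator).
#'
#' @param ranking data frame from [rank_regulators()].
#' @param activity,enrichment the activity and enrichment tables.
#' @param alpha FDR threshold applied to both FDRs (default 0.05).
#' @param weight_floor minimum weight for a TF to count as selected
#'   (default 1e-6).
#' @return character vector of TF ids in rank order.
#' @export
significant_set <- function(ranking, activity, enrichment, alpha = 0.05,
                            weight_floor = 1e-6) {
  fdr_v <- setNames(activity$fdr_viper, activity$tf)[ranking$tf]
  fdr_b <- setNames(enrichment$fdr_biomarker, enrichment$tf)[ranking$tf]
  sel <- ranking$weight > weight_floor &
    !is.na(fdr_v) & fdr_v <= alpha &
    !is.na(fdr_b) & fdr_b <= alpha
  ranking$tf[sel]
}

#' Cumulative biomarker coverage along a ranking
#'
#' The k-th value is the number of distinct biomarker genes targeted by the
#' union of the first k TFs' regulons; the curve is nondecreasing and ends
#' at the total coverable count.
#'
#' @param tfs character vector of TF ids, best first.
#' @param network a [grn()] object.
#' @param biomarker character vector of biomarker gene ids.
#' @return integer vector of cumulative coverage, one value per rank prefix.
#' @export
coverage_curve <- function(tfs, network, biomarker) {
  stopifnot(inherits(network, "netfactor_grn"), length(tfs) > 0)
  biomarker <- unique(as.character(biomarker))
  regs <- regulons(network)
  covered <- character(0)
  curve <- integer(length(tfs))
  for (k in seq_along(tfs)) {
    r <- regs[[tfs[k]]]
    if (!is.null(r)) covered <- union(covered, intersect(r$target, biomarker))
    curve[k] <- length(covered)
  }
  curve
}
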