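# Regulon-biomarker over-representation (Fisher's exact test + BH).

#' Fisher's exact test for regulon-biomarker overlap
#'
#' One-sided (greater) Fisher's exact test of the overlap between a TF's
#' regulon and the biomarker gene set within a gene universe: the p-value
#' is the hypergeometric upper tail `P(X >= k)` with `N = |universe|`,
#' `K = |regulon|`, `n = |biomarker in universe|`, `k = |overlap|`. Only
#' over-representation is of interest (under-representation carries no
#' evidence of regulation). Ids outside the universe are dropped with a
#' warning.
#'
#' @param regulon character vector of a TF's target gene ids.
#' @param biomarker character vector of biomarker gene ids.
#' @param universe character vector of background gene ids (>= 2).
#' @return list with `overlap`, `regulon_size`, `biomarker_size` (in
#'   universe) and `p`.
#' @export
fisher_overlap <- function(regulon, biomarker, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2) stop_input("universe must contain >= 2 genes")
  regulon <- unique(as.character(regulon))
  biomarker <- unique(as.character(biomarker))
  out_r <- setdiff(regulon, universe)
  out_b <- setdiff(biomarker, universe)
  if (length(out_r) || length(out_b))
    warning(length(out_r) + length(out_b),
            " id(s) outside the universe dropped from the test")
  regulon <- intersect(regulon, universe)
  biomarker <- intersect(biomarker, universe)
  k <- length(intersect(regulon, biomarker))
  list(overlap = k, regulon_size = length(regulon),
       biomarker_size = length(biomarker),
       p = hyper_upper_tail(k, length(regulon), length(biomarker),
                            length(universe)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector
#' (`stats::p.adjust(method = "BH")` with input validation).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Biomarker enrichment of every regulon in a network
#'
#' Runs [fisher_overlap()] for each TF regulon against the biomarker and
#' adjusts across TFs with [bh_adjust()], yielding FDR_BIOMARKER. The
#' default universe is the set of all distinct target genes of the network:
#' the test asks about regulation within the GRN, and biomarker genes
#' outside the GRN cannot be regulated by its TFs in the first place --
#' these "uncoverable" genes are reported separately rather than silently
#' dropped. `universe = "measured"` uses all measured genes instead.
#'
#' @param network a [grn()] object.
#' @param biomarker character vector of biomarker gene ids (nonempty).
#' @param universe `"grn"` (default: all GRN target genes) or `"measured"`.
#' @param measured character vector of all measured gene ids (required for
#'   `universe = "measured"`).
#' @return data frame with columns `tf`, `regulon_size`, `overlap`,
#'   `p_fisher`, `fdr_biomarker`; attribute `uncoverable` lists the
#'   biomarker genes absent from the universe.
#' @export
enrich_all <- function(network, biomarker, universe = c("grn", "measured"),
                       measured = NULL) {
  stopifnot(inherits(network, "netfactor_grn"))
  universe <- match.arg(universe)
  biomarker <- unique(as.character(biomarker))
  if (!length(biomarker)) stop_input("biomarker gene set is empty")
  uni <- if (universe == "grn") {
    sort(unique(network$edges$target), method = "radix")
  } else {
    if (is.null(measured)) stop_input("universe = 'measured' needs `measured` gene ids")
    sort(unique(as.character(measured)), method = "radix")
  }
  uncoverable <- setdiff(biomarker, uni)
  if (!length(intersect(biomarker, uni)))
    stop_input("biomarker and universe are disjoint: nothing enrichable")
  regs <- regulons(network)
  rows <- lapply(names(regs), function(tf) {
    fo <- suppressWarnings(
      fisher_overlap(regs[[tf]]$target, biomarker, uni))
    data.frame(tf = tf, regulon_size = fo$regulon_size, overlap = fo$overlap,
               p_fisher = fo$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_biomarker <- bh_adjust(out$p_fisher)
  out <- out[order(out$tf, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "uncoverable") <- sort(uncoverable, method = "radix")
  attr(out, "universe_size") <- length(uni)
  class(out) <- c("netfactor_enrichment", "data.frame")
  out
}

#' Read / write an enrichment table (TSV)
#'
#' Format: `tf<TAB>regulon_size<TAB>overlap<TAB>p_fisher<TAB>fdr_biomarker`.
#'
#' @param path file path.
#' @export
read_enrichment <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "fdr_biomarker") %in% names(d)))
    stop_input("enrichment file needs 'tf' and 'fdr_biomarker' columns: ", path)
  class(d) <- c("netfactor_enrichment", "data.frame")
  d
}

#' @rdname read_enrichment
#' @param enrichment data frame from [enrich_all()].
#' @export
write_enrichment <- function(enrichment, path) {
  d <- as.data.frame(enrichment)
  for (cn in intersect(c("p_fisher", "fdr_biomarker"), names(d)))
    d[[cn]] <- fmt_num(d[[cn]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
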