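# Readers and writers: expression TSV, labels TSV, GMT / plain gene lists,
# results TSV + JSON summary. All files are UTF-8, tab-separated, Unix
# newlines; gene ids are opaque strings.

#' Read an expression matrix (TSV)
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids. Duplicate gene ids and missing cells are
#' hard errors (with the offending id / coordinates), not warnings: every
#' downstream stage assumes a complete matrix.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(d) || ncol(d) < 2) stop_input("empty or malformed expression file: ", path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop_input("duplicated gene id in ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric expression values in ", path)
  rownames(m) <- ids
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_input("missing value in ", path, " at gene '", rownames(m)[idx[1]],
               "', sample '", colnames(m)[idx[2]], "'")
  }
  m
}

#' @rdname read_expression
#' @param expr numeric matrix to write.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  d <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample class labels (TSV)
#'
#' Two-column TSV with header `sample<TAB>class`; classes are `case` or
#' `control`.
#'
#' @param path file path.
#' @return named character vector, sample id -> class.
#' @export
read_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop_input("labels file needs two columns: ", path)
  lab <- setNames(as.character(d[[2]]), as.character(d[[1]]))
  bad <- setdiff(unique(lab), c("case", "control"))
  if (length(bad))
    stop_input("labels must be 'case'/'control', got: ", paste(bad, collapse = ", "))
  lab
}

#' @rdname read_labels
#' @param labels named character vector to write.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(sample = names(labels), class = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets (GMT or plain list)
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; a line with
#' fewer than three fields is a format error (reported with its line
#' number). Duplicate genes within a set are deduplicated with a warning.
#' `format = "list"` reads a one-gene-per-line file into a single unnamed
#' set.
#'
#' @param path file path.
#' @param format `"gmt"` (default) or `"list"`.
#' @return named list of character vectors (`gmt`), or a character vector
#'   (`list`).
#' @export
read_gene_sets <- function(path, format = c("gmt", "list")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_input("empty gene set file: ", path)
  if (format == "list") {
    return(unique(trimws(lines)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_input("malformed GMT line ", i, " in ", path,
                 " (need name, description, >= 1 gene)")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the full results of a fit
#'
#' Produces `<prefix>_results.tsv` -- one row per TF with columns
#' `tf`, `nes`, `fdr_viper`, `overlap`, `fdr_biomarker`, `lasso_weight`,
#' `rank`, `selected`, ordered by rank -- and `<prefix>_summary.json` with
#' the configuration echo (including the seed), the LP objective, both
#' coverage curves, the significant set and the uncovered biomarker genes.
#' Floats are written at 6 significant digits; reruns with the same seed
#' produce byte-identical files.
#'
#' @param fit a [netfactor()] fit.
#' @param path_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_results <- function(fit, path_prefix) {
  stopifnot(inherits(fit, "netfactor"))
  d <- as.data.frame(fit)
  for (cn in c("nes", "fdr_viper", "fdr_biomarker", "lasso_weight"))
    d[[cn]] <- fmt_num(d[[cn]])
  tsv <- paste0(path_prefix, "_results.tsv")
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  js <- paste0(path_prefix, "_summary.json")
  sel <- fit$selection
  summary <- list(
    config = fit$config,
    n_edges = nrow(fit$grn$edges),
    n_tfs_scored = sum(!is.na(fit$activity$nes)),
    objective = sel$objective,
    significant = as.list(sel$significant),
    uncovered = as.list(sel$uncovered),
    uncoverable = as.list(attr(fit$enrichment, "uncoverable")),
    coverage_curves = list(lasso = sel$curves$lasso, greedy = sel$curves$greedy)
  )
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
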