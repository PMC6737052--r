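#' Identify TF regulators of an expression biomarker
#'
#' Runs the four-stage regulator-identification pipeline on an expression
#' matrix with case/control labels, a candidate TF list and a biomarker
#' gene set:
#'
#' 1. **Network inference** (skipped when `network` is supplied): an
#'    ARACNE-style consensus GRN via [bootstrap_consensus()], with
#'    regulation modes from [assign_modes()].
#' 2. **Differential TF activity**: regulon enrichment of the
#'    case-vs-control signature against a permutation null
#'    ([tf_activity()]), giving each TF an NES and FDR (`fdr_viper`).
#' 3. **Biomarker enrichment**: Fisher's exact test of each regulon against
#'    the biomarker with BH correction ([enrich_all()]), giving
#'    `fdr_biomarker`.
#' 4. **Regulator selection**: the coverage matrix with entries
#'    `(1 - fdr_viper) (1 - fdr_biomarker)` on regulon membership feeds the
#'    L1-relaxed set-cover LP ([solve_l1_cover()]); TFs are ranked by the
#'    resulting weights, the dual-FDR filter ([significant_set()]) yields
#'    the final regulator set, and greedy/LP coverage curves are computed.
#'
#' @param expr numeric matrix, genes x samples (gene rownames, sample
#'   colnames).
#' @param labels sample classes (`"case"`/`"control"`), named by sample id
#'   or aligned with the columns.
#' @param tf_list candidate TF gene ids.
#' @param biomarker biomarker gene ids.
#' @param network optional precomputed [grn()]; if given, stage 1 is
#'   skipped (modes are assigned from `expr` when absent).
#' @param bootstraps GRN bootstrap count (default 100).
#' @param n_bins MI bin count (default derived from the sample count).
#' @param dpi_tolerance DPI tolerance (default 0).
#' @param mi_threshold_p consensus edge significance level (default 0.05).
#' @param permutations activity permutation count (default 1000).
#' @param null_model `"samples"` (default; independent samples) or
#'   `"genes"` (dependent samples).
#' @param signature_method `"welch_t"` (default) or `"signed_rank_z"`.
#' @param alpha dual-FDR significance threshold (default 0.05).
#' @param universe enrichment universe, `"grn"` (default) or `"measured"`.
#' @param weight_floor minimal LP weight for selection (default 1e-6).
#' @param seed master seed; all randomness (bootstraps, permutations)
#'   derives child seeds from it, so a fixed seed gives byte-identical
#'   outputs.
#' @param verbose log each stage to stderr (default TRUE).
#' @return an object of class `netfactor`: list with `grn`, `activity`,
#'   `enrichment`, `selection` (weights, objective, ranking, significant
#'   set, greedy baseline, coverage curves, uncovered genes) and `config`.
#'   Methods: [print.netfactor()], [summary.netfactor()],
#'   [coef.netfactor()], [plot.netfactor()]; serialize with
#'   [write_results()].
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 1, n_tfs = 8, n_genes = 80,
#'                         regulon_size = 12, n_cases = 20, n_controls = 20,
#'                         n_from_drivers = 15, n_decoys = 5)
#' fit <- netfactor(study$expr, study$labels, study$truth$tfs,
#'                  study$biomarker, bootstraps = 10, permutations = 100,
#'                  seed = 1, verbose = FALSE)
#' summary(fit)
#' }
#' @export
netfactor <- function(expr, labels, tf_list, biomarker, network = NULL,
                      bootstraps = 100, n_bins = NULL, dpi_tolerance = 0,
                      mi_threshold_p = 0.05, permutations = 1000,
                      null_model = c("samples", "genes"),
                      signature_method = c("welch_t", "signed_rank_z"),
                      alpha = 0.05, universe = c("grn", "measured"),
                      weight_floor = 1e-6, seed = 1, verbose = TRUE) {
  null_model <- match.arg(null_model)
  signature_method <- match.arg(signature_method)
  universe <- match.arg(universe)
  check_expression(expr)
  labels <- check_labels(labels, expr)
  n_bins <- n_bins %||% default_bins(ncol(expr))
  say <- function(...) if (verbose) message("[netfactor] ", ...)

  config <- list(bootstraps = bootstraps, n_bins = n_bins,
                 dpi_tolerance = dpi_tolerance,
                 mi_threshold_p = mi_threshold_p,
                 permutations = permutations, null_model = null_model,
                 signature_method = signature_method, alpha = alpha,
                 universe = universe, weight_floor = weight_floor,
                 seed = seed,
                 network_supplied = !is.null(network))

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "': ", conditionMessage(e)),
                          class = class(e)[1]))
    })
  }

  if (is.null(network)) {
    say("inferring consensus GRN (", bootstraps, " bootstraps)")
    network <- stage("grn_inference",
      bootstrap_consensus(expr, tf_list, n_boot = bootstraps,
                          mi_threshold_p = mi_threshold_p, n_bins = n_bins,
                          dpi_tolerance = dpi_tolerance, seed = seed))
  } else {
    say("using supplied network, inference skipped")
    stopifnot(inherits(network, "netfactor_grn"))
  }
  if (all(is.na(network$edges$mode))) {
    network <- stage("assign_modes", assign_modes(expr, network))
  }
  say("GRN: ", nrow(network$edges), " edges, ",
      length(unique(network$edges$tf)), " TFs, ",
      length(unique(network$edges$target)), " targets")
  if (!nrow(network$edges)) stop_input("inferred network is empty")

  say("scoring TF activity (", permutations, " ", null_model,
      "-permutations)")
  activity <- stage("activity",
    tf_activity(expr, labels, network, null_model = null_model,
                n_perm = permutations, seed = child_seed(seed, 500001),
                signature_method = signature_method))
  say("TFs scored: ", sum(!is.na(activity$nes)), "/", nrow(activity))

  say("testing regulon-biomarker enrichment")
  enrichment <- stage("biomarker_enrichment",
    enrich_all(network, biomarker, universe = universe,
               measured = rownames(expr)))
  say("coverable biomarker genes in universe: ",
      length(intersect(biomarker, unique(network$edges$target))), "/",
      length(unique(biomarker)))

  say("solving L1-relaxed set cover")
  A <- stage("selection",
    build_coverage_matrix(network, activity, enrichment, biomarker))
  sol <- stage("selection", solve_l1_cover(A))
  ranking <- rank_regulators(sol$weights, activity, enrichment)
  significant <- significant_set(ranking, activity, enrichment,
                                 alpha = alpha, weight_floor = weight_floor)
  greedy <- greedy_cover(network, biomarker)
  curves <- list(lasso = coverage_curve(ranking$tf, network, biomarker),
                 greedy = greedy$curve)
  say("objective ", format(sol$objective, digits = 6), "; significant set: ",
      if (length(significant)) paste(significant, collapse = ", ") else "(empty)")

  selection <- list(A = A, weights = sol$weights, objective = sol$objective,
                    ranking = ranking, significant = significant,
                    greedy = greedy, curves = curves,
                    uncovered = attr(A, "uncovered"))
  structure(list(call = match.call(), config = config, grn = network,
                 activity = activity, enrichment = enrichment,
                 selection = selection),
            class = "netfactor")
}

#' @export
print.netfactor <- function(x, ...) {
  cat("netfactor fit\n")
  cat("  GRN: ", nrow(x$grn$edges), " edges (",
      length(unique(x$grn$edges$tf)), " TFs -> ",
      length(unique(x$grn$edges$target)), " targets)\n", sep = "")
  cat("  TFs scored for activity:", sum(!is.na(x$activity$nes)), "\n")
  cat("  Set-cover objective:", format(x$selection$objective, digits = 6), "\n")
  sig <- x$selection$significant
  cat("  Significant regulators (dual FDR <= ", x$config$alpha, "): ",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' Results table of a fit
#'
#' One row per scored TF, ordered by rank: NES and FDRs from the activity
#' and enrichment stages, biomarker overlap, LP weight, rank and whether
#' the TF passed the dual-FDR selection filter.
#'
#' @param x a [netfactor()] fit.
#' @param ... unused.
#' @export
as.data.frame.netfactor <- function(x, ...) {
  r <- x$selection$ranking
  act <- x$activity; enr <- x$enrichment
  d <- data.frame(
    tf = r$tf,
    nes = setNames(act$nes, act$tf)[r$tf],
    fdr_viper = setNames(act$fdr_viper, act$tf)[r$tf],
    overlap = setNames(enr$overlap, enr$tf)[r$tf],
    fdr_biomarker = setNames(enr$fdr_biomarker, enr$tf)[r$tf],
    lasso_weight = r$weight,
    rank = r$rank,
    selected = r$tf %in% x$selection$significant,
    stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' @export
summary.netfactor <- function(object, n = 7, ...) {
  d <- as.data.frame(object)
  cat("Top", min(n, nrow(d)), "TF regulators by set-cover weight:\n")
  print(head(d, n), digits = 4, row.names = FALSE)
  cat("\nBiomarker coverage: ",
      max(object$selection$curves$lasso), " of ",
      max(object$selection$curves$lasso) + length(object$selection$uncovered),
      " genes coverable; uncovered: ",
      length(object$selection$uncovered), "\n", sep = "")
  invisible(d)
}

#' @export
coef.netfactor <- function(object, ...) object$selection$weights

#' Coverage curves of a fit
#'
#' Plots cumulative biomarker coverage against the number of selected TFs
#' for the LP (weight-ranked) and greedy orderings.
#'
#' @param x a [netfactor()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.netfactor <- function(x, ...) {
  cl <- x$selection$curves$lasso
  cg <- x$selection$curves$greedy
  k <- max(length(cl), length(cg))
  m <- cbind(lasso = c(cl, rep(max(cl), k - length(cl))),
             greedy = c(cg, rep(max(cg), k - length(cg))))
  matplot(seq_len(k), m, type = "s", lty = 1, lwd = 2,
          col = c("#1b6ca8", "#c84b31"),
          xlab = "number of TFs (ranked)",
          ylab = "biomarker genes covered", ...)
  legend("bottomright", legend = c("L1 set cover", "greedy"),
         col = c("#1b6ca8", "#c84b31"), lwd = 2, bty = "n")
  invisible(x)
}
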