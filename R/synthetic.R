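# Ground-truthed synthetic data: planted GRN, expression with
# class-dependent driver activity, biomarker gene set.

#' Generate a planted regulatory ground truth
#'
#' Draws a TF -> target map in which every TF regulates `regulon_size`
#' targets (modes +/-1 with equal probability, a common linear effect size
#' `beta`), and `n_drivers` "driver" TFs share a common core of
#' `round(overlap_frac * regulon_size)` targets -- the redundancy that the
#' set-cover step is designed to resolve. Driver activity is shifted by
#' `delta` in cases when expression is simulated.
#'
#' @param n_tfs number of TFs (default 20).
#' @param n_genes number of non-TF genes (default 500).
#' @param regulon_size targets per TF (default 40).
#' @param n_drivers number of driver TFs (default 2; the first TFs).
#' @param overlap_frac pairwise fraction of targets shared between driver
#'   regulons (default 0.25).
#' @param beta linear TF -> target effect size (> 0, default 0.8).
#' @param delta case-class shift of driver TF activity (default 1.5).
#' @param sigma residual noise standard deviation (> 0, default 1).
#' @param seed integer seed.
#' @return object of class `netfactor_truth`: list with `tfs`, `genes`,
#'   `regulons` (per TF: data frame `target`, `mode`, `beta`), `drivers`,
#'   `delta`, `sigma`, `seed`.
#' @export
generate_truth <- function(n_tfs = 20, n_genes = 500, regulon_size = 40,
                           n_drivers = 2, overlap_frac = 0.25, beta = 0.8,
                           delta = 1.5, sigma = 1, seed = 1) {
  if (n_drivers > n_tfs) stop_input("n_drivers must be <= n_tfs")
  if (regulon_size > n_genes) stop_input("regulon_size must be <= n_genes")
  if (overlap_frac < 0 || overlap_frac > 1)
    stop_input("overlap_frac must be in [0, 1]")
  if (beta <= 0 || sigma <= 0) stop_input("beta and sigma must be > 0")
  n_shared <- round(overlap_frac * regulon_size)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  genes <- sprintf("G%04d", seq_len(n_genes))
  drivers <- tfs[seq_len(n_drivers)]

  set.seed(child_seed(seed, 0))
  shared <- if (n_drivers >= 2) sample(genes, n_shared) else character(0)
  n_own <- if (n_drivers >= 2) regulon_size - n_shared else regulon_size
  if (n_drivers * n_own + n_shared > n_genes)
    stop_input("overlap_frac infeasible: driver regulons cannot be drawn disjointly")
  # non-shared driver targets come from a shrinking pool so driver regulons
  # overlap pairwise by exactly the shared core
  own_pool <- setdiff(genes, shared)
  regs <- vector("list", n_tfs)
  names(regs) <- tfs
  for (i in seq_len(n_tfs)) {
    set.seed(child_seed(seed, i))
    if (tfs[i] %in% drivers) {
      own <- if (n_own > 0) sample(own_pool, n_own) else character(0)
      own_pool <- setdiff(own_pool, own)
      tgt <- c(shared, own)
    } else {
      tgt <- sample(genes, regulon_size)
    }
    mode <- sample(c(-1L, 1L), regulon_size, replace = TRUE)
    regs[[i]] <- data.frame(target = tgt, mode = mode, beta = beta,
                            stringsAsFactors = FALSE)
  }
  structure(list(tfs = tfs, genes = genes, regulons = regs,
                 drivers = drivers, delta = delta, sigma = sigma, seed = seed),
            class = "netfactor_truth")
}

#' Simulate expression data from a planted truth
#'
#' TF expression is standard normal, shifted by `delta` in case samples for
#' driver TFs. Each target gene is the mode- and beta-weighted sum of its
#' regulating TFs plus Gaussian noise with sd `sigma`; unregulated genes
#' are pure noise. The model is linear-Gaussian: the pipeline consumes
#' normalized expression through rank-based statistics, so count-level
#' realism is orthogonal to what it tests. `model = "poisson_log1p"`
#' instead emits `log1p` of Poisson counts with rate `exp(latent)`, for a
#' crude count-scale variant.
#'
#' @param truth a [generate_truth()] object.
#' @param n_cases,n_controls sample counts (>= 2 each; defaults 75/75,
#'   a 150-sample case-control cohort scale).
#' @param seed integer seed.
#' @param model `"gaussian"` (default) or `"poisson_log1p"`.
#' @return list with `expr` (matrix, TFs then genes x samples) and `labels`
#'   (named character vector, `"case"`/`"control"`).
#' @export
simulate_expression <- function(truth, n_cases = 75, n_controls = 75, seed = 1,
                                model = c("gaussian", "poisson_log1p")) {
  stopifnot(inherits(truth, "netfactor_truth"))
  model <- match.arg(model)
  if (n_cases < 2 || n_controls < 2) stop_input("need >= 2 samples per class")
  n <- n_cases + n_controls
  samples <- sprintf("S%04d", seq_len(n))
  labels <- setNames(rep(c("case", "control"), c(n_cases, n_controls)), samples)

  set.seed(child_seed(seed, 10001))
  TFX <- matrix(rnorm(length(truth$tfs) * n), length(truth$tfs), n,
                dimnames = list(truth$tfs, samples))
  TFX[truth$drivers, labels == "case"] <-
    TFX[truth$drivers, labels == "case"] + truth$delta
  GX <- matrix(rnorm(length(truth$genes) * n, sd = truth$sigma),
               length(truth$genes), n,
               dimnames = list(truth$genes, samples))
  for (tf in truth$tfs) {
    r <- truth$regulons[[tf]]
    GX[r$target, ] <- GX[r$target, ] +
      (r$mode * r$beta) %o% TFX[tf, ]
  }
  expr <- rbind(TFX, GX)
  if (model == "poisson_log1p") {
    expr <- matrix(log1p(rpois(length(expr), lambda = exp(expr))),
                   nrow(expr), ncol(expr), dimnames = dimnames(expr))
  }
  list(expr = expr, labels = labels)
}

#' Draw a biomarker gene set from a planted truth
#'
#' Samples `n_from_drivers` genes from the union of the driver regulons and
#' `n_decoys` decoy genes from the genes targeted by no driver (decoys may
#' still be regulated by non-driver TFs, or by nothing) -- emulating a
#' real-world biomarker that is mostly, but not entirely, downstream of its
#' true regulators.
#'
#' @param truth a [generate_truth()] object.
#' @param n_from_drivers genes drawn from the driver regulon union
#'   (default 60).
#' @param n_decoys decoy genes (default 30).
#' @param seed integer seed.
#' @return character vector of biomarker gene ids.
#' @export
derive_biomarker <- function(truth, n_from_drivers = 60, n_decoys = 30,
                             seed = 1) {
  stopifnot(inherits(truth, "netfactor_truth"))
  driver_union <- unique(unlist(lapply(truth$regulons[truth$drivers],
                                       `[[`, "target")))
  if (n_from_drivers > length(driver_union))
    stop_input("n_from_drivers exceeds the driver regulon union (",
               length(driver_union), ")")
  decoy_pool <- setdiff(truth$genes, driver_union)
  if (n_decoys > length(decoy_pool))
    stop_input("not enough decoy genes (", length(decoy_pool), " available)")
  set.seed(child_seed(seed, 20001))
  from_drivers <- sample(driver_union, n_from_drivers)
  decoys <- sample(decoy_pool, n_decoys)
  sort(c(from_drivers, decoys), method = "radix")
}

#' Ground-truth network of a planted truth
#'
#' Converts the planted regulons into a [grn()] object (unit MI and
#' support, true modes) -- the oracle network for testing the activity,
#' enrichment and selection stages independently of network inference.
#'
#' @param truth a [generate_truth()] object.
#' @return a [grn()] object.
#' @export
grn_from_truth <- function(truth) {
  stopifnot(inherits(truth, "netfactor_truth"))
  ed <- do.call(rbind, lapply(names(truth$regulons), function(tf) {
    r <- truth$regulons[[tf]]
    data.frame(tf = tf, target = r$target, mi = 1, support = 1,
               mode = r$mode, stringsAsFactors = FALSE)
  }))
  grn(ed, tfs = truth$tfs)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper drawing a planted truth, an expression matrix with
#' labels, and a biomarker gene set under the package's default study
#' conditions (20 TFs, 500 genes, regulons of 40, 2 drivers sharing 25% of
#' targets, beta 0.8, delta 1.5, sigma 1, 75 cases / 75 controls, 60 + 30
#' biomarker genes).
#'
#' @param seed integer seed driving every stage.
#' @param ... overrides passed to [generate_truth()].
#' @param n_cases,n_controls,n_from_drivers,n_decoys study-size overrides.
#' @return list with `truth`, `expr`, `labels`, `biomarker`.
#' @export
simulate_study <- function(seed = 1, ..., n_cases = 75, n_controls = 75,
                           n_from_drivers = 60, n_decoys = 30) {
  truth <- generate_truth(seed = seed, ...)
  sim <- simulate_expression(truth, n_cases = n_cases, n_controls = n_controls,
                             seed = seed)
  biomarker <- derive_biomarker(truth, n_from_drivers = n_from_drivers,
                                n_decoys = n_decoys, seed = seed)
  list(truth = truth, expr = sim$expr, labels = sim$labels,
       biomarker = biomarker)
}
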