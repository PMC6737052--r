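# TF activity: differential-expression signature, normal scores, regulon
# enrichment score, permutation null.

#' Differential-expression signature between classes
#'
#' Computes one signed statistic per gene contrasting case against control
#' samples (positive = higher in cases). `welch_t` is the per-gene Welch
#' t-statistic; `signed_rank_z` is the normal-approximated Wilcoxon
#' rank-sum z of the case ranks (tie-corrected).
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels sample classes (`"case"`/`"control"`), named by sample id
#'   or aligned with the columns. Each class needs >= 2 samples.
#' @param method `"welch_t"` (default) or `"signed_rank_z"`.
#' @return named numeric vector, one statistic per gene.
#' @export
compute_signature <- function(expr, labels, method = c("welch_t", "signed_rank_z")) {
  method <- match.arg(method)
  check_expression(expr)
  lab <- check_labels(labels, expr)
  n1 <- sum(lab == "case"); n2 <- sum(lab == "control")
  if (n1 < 2 || n2 < 2) stop_input("each class needs >= 2 samples")
  if (method == "welch_t") {
    X1 <- expr[, lab == "case", drop = FALSE]
    X2 <- expr[, lab == "control", drop = FALSE]
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
    den <- sqrt(v1 / n1 + v2 / n2)
    if (any(den == 0))
      warning(sum(den == 0), " gene(s) with zero pooled variance: statistic set to 0")
    stat <- ifelse(den > 0, (m1 - m2) / den, 0)
  } else {
    rk <- t(apply(expr, 1, rank))
    N <- n1 + n2
    W <- rowSums(rk[, lab == "case", drop = FALSE])
    ties <- apply(expr, 1, function(v) {
      tt <- table(v); sum(tt^3 - tt)
    })
    sigma2 <- n1 * n2 / 12 * ((N + 1) - ties / (N * (N - 1)))
    if (any(sigma2 == 0))
      warning(sum(sigma2 == 0), " gene(s) with zero rank variance: statistic set to 0")
    stat <- ifelse(sigma2 > 0, (W - n1 * (N + 1) / 2) / sqrt(sigma2), 0)
  }
  setNames(as.numeric(stat), rownames(expr))
}

#' Rank-to-normal scores of a signature
#'
#' Maps the signature onto standard-normal quantiles,
#' `z_g = qnorm(rank_g / (G + 1))` with average ranks for ties. The
#' transform is order-preserving and stabilizes the regulon enrichment sum
#' against heavy-tailed statistics.
#'
#' @param signature named numeric vector (from [compute_signature()]).
#' @return named numeric vector of normal scores.
#' @export
normal_scores <- function(signature) {
  if (length(signature) < 2) stop_input("need >= 2 genes")
  setNames(qnorm(rank(signature) / (length(signature) + 1)), names(signature))
}

#' Regulon enrichment score
#'
#' Signed, variance-normalized enrichment of a TF's regulon in the
#' signature: `es = sum(mode_j * z_j) / sqrt(m)` over the `m` regulon
#' targets present in the signature with non-zero mode, where `z` are the
#' normal scores. Positive scores mean the TF's activated targets sit high
#' in the case-vs-control signature (TF more active in cases). Under a
#' random signature the score has mean ~0 and variance ~1, so scores are
#' comparable across regulon sizes.
#'
#' @param signature named numeric vector.
#' @param regulon data frame with columns `target`, `mode`.
#' @return enrichment score, or NA if no usable target remains.
#' @export
nes_score <- function(signature, regulon) {
  z <- normal_scores(signature)
  es_from_scores(z, regulon)
}

es_from_scores <- function(z, regulon) {
  r <- regulon[!is.na(regulon$mode) & regulon$mode != 0 &
                 regulon$target %in% names(z), , drop = FALSE]
  m <- nrow(r)
  if (!m) return(NA_real_)
  sum(r$mode * z[r$target]) / sqrt(m)
}

# regulon list -> sparse mode matrix (genes x TFs) for vectorized scoring
mode_matrix <- function(regs, gene_ids) {
  M <- matrix(0, length(gene_ids), length(regs),
              dimnames = list(gene_ids, names(regs)))
  for (tf in names(regs)) {
    r <- regs[[tf]]
    r <- r[!is.na(r$mode) & r$mode != 0 & r$target %in% gene_ids, , drop = FALSE]
    if (nrow(r)) M[r$target, tf] <- r$mode
  }
  M
}

# Vectorized Welch t for many label permutations. C is an n x B 0/1 case
# indicator matrix; every column has the same case count.
welch_t_perm <- function(expr, C) {
  n1 <- sum(C[, 1]); n2 <- nrow(C) - n1
  X <- expr; X2 <- expr^2
  S1 <- X %*% C; S2 <- X %*% (1 - C)
  Q1 <- X2 %*% C; Q2 <- X2 %*% (1 - C)
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (Q2 - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  den <- sqrt(v1 / n1 + v2 / n2)
  T <- (m1 - m2) / den
  T[den == 0] <- 0
  T
}

rank_z_perm <- function(rk, sigma2, n1, N, C) {
  W <- rk %*% C
  Z <- (W - n1 * (N + 1) / 2) / sqrt(sigma2)
  Z[sigma2 == 0, ] <- 0
  Z
}

#' Permutation null for TF activity scores
#'
#' Builds a two-sided empirical p-value per TF for its regulon enrichment
#' score. The `samples` null permutes the class labels and recomputes the
#' signature and the score for each permutation (appropriate for
#' independent samples); the `genes` null keeps the observed signature and
#' permutes the gene labels (for designs with dependent samples). p-values
#' use the add-one estimator `(1 + #{|es_perm| >= |es_obs|}) / (n_perm + 1)`;
#' when fewer distinct label permutations than `n_perm` exist, all distinct
#' ones are enumerated instead (with a warning) and the plain fraction is
#' reported.
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels sample classes.
#' @param regs named list of regulons (data frames `target`, `mode`), e.g.
#'   [regulons()] output.
#' @param null_model `"samples"` (default) or `"genes"`.
#' @param n_perm number of permutations (>= 10, default 1000).
#' @param seed integer seed (one child seed per permutation).
#' @param signature_method passed to [compute_signature()].
#' @return list with `p` (named p-values, NA for unscorable TFs), `es`
#'   (observed scores) and `n_perm_used`.
#' @export
permutation_null <- function(expr, labels, regs,
                             null_model = c("samples", "genes"),
                             n_perm = 1000, seed = 1,
                             signature_method = "welch_t") {
  null_model <- match.arg(null_model)
  if (n_perm < 10) stop_input("n_perm must be >= 10")
  check_expression(expr)
  lab <- check_labels(labels, expr)
  sig <- suppressWarnings(compute_signature(expr, lab, signature_method))
  z_obs <- normal_scores(sig)
  M <- mode_matrix(regs, rownames(expr))
  m <- colSums(M != 0)
  es_obs <- setNames(rep(NA_real_, length(regs)), names(regs))
  ok <- m > 0
  es_obs[ok] <- as.numeric(crossprod(M[, ok, drop = FALSE], z_obs)) / sqrt(m[ok])

  n <- ncol(expr)
  n_case <- sum(lab == "case")
  exhaustive <- FALSE
  if (null_model == "samples") {
    n_distinct <- choose(n, n_case)
    if (n_distinct <= n_perm) {
      warning("only ", n_distinct, " distinct label permutations; using all of them")
      sets <- combn(n, n_case)
      C <- matrix(0, n, ncol(sets))
      C[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n_case))] <- 1
      exhaustive <- TRUE
    } else {
      C <- matrix(0, n, n_perm)
      for (b in seq_len(n_perm)) {
        set.seed(child_seed(seed, b))
        C[lab[sample.int(n)] == "case", b] <- 1
      }
    }
    if (signature_method == "welch_t") {
      T <- welch_t_perm(expr, C)
    } else {
      rk <- t(apply(expr, 1, rank))
      ties <- apply(expr, 1, function(v) { tt <- table(v); sum(tt^3 - tt) })
      sigma2 <- n_case * (n - n_case) / 12 * ((n + 1) - ties / (n * (n - 1)))
      T <- rank_z_perm(rk, sigma2, n_case, n, C)
    }
    Z <- qnorm(apply(T, 2, rank) / (nrow(expr) + 1))
  } else {
    G <- nrow(expr)
    Z <- matrix(0, G, n_perm)
    for (b in seq_len(n_perm)) {
      set.seed(child_seed(seed, b))
      Z[, b] <- z_obs[sample.int(G)]
    }
  }
  rownames(Z) <- rownames(expr)
  B <- ncol(Z)
  ES <- crossprod(M[, ok, drop = FALSE], Z) / sqrt(m[ok]) # TFs x perms
  p <- setNames(rep(NA_real_, length(regs)), names(regs))
  exceed <- rowSums(abs(ES) >= abs(es_obs[ok]) - 1e-12)
  p[ok] <- if (exhaustive) exceed / B else (1 + exceed) / (B + 1)
  list(p = p, es = es_obs, n_perm_used = B)
}

#' TF differential activity with permutation FDR
#'
#' Scores every TF regulon of a network against the case-vs-control
#' signature: the normalized enrichment score (NES; positive = more active
#' in cases), a two-sided permutation p-value, and the Benjamini-Hochberg
#' FDR across all scorable TFs. TFs whose effective regulon is empty (no
#' target with non-zero mode present in the data) are reported with NA and
#' excluded from the FDR correction so they do not dilute it.
#'
#' @inheritParams permutation_null
#' @param network a [grn()] with modes assigned (see [assign_modes()]).
#' @return data frame with columns `tf`, `nes`, `p_viper`, `fdr_viper`.
#' @export
tf_activity <- function(expr, labels, network,
                        null_model = c("samples", "genes"),
                        n_perm = 1000, seed = 1,
                        signature_method = "welch_t") {
  stopifnot(inherits(network, "netfactor_grn"))
  if (all(is.na(network$edges$mode)))
    stop_input("network has no modes assigned; run assign_modes() first")
  regs <- regulons(network)
  nul <- permutation_null(expr, labels, regs, null_model = null_model,
                          n_perm = n_perm, seed = seed,
                          signature_method = signature_method)
  out <- data.frame(tf = names(nul$p), nes = as.numeric(nul$es),
                    p_viper = as.numeric(nul$p),
                    fdr_viper = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(out$p_viper)
  out$fdr_viper[ok] <- p.adjust(out$p_viper[ok], method = "BH")
  out <- out[order(out$tf, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("netfactor_activity", "data.frame")
  out
}

#' Read / write an activity table (TSV)
#'
#' Format: `tf<TAB>nes<TAB>p_viper<TAB>fdr_viper`, NA for unscorable TFs.
#'
#' @param path file path.
#' @export
read_activity <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "nes") %in% names(d)))
    stop_input("activity file needs 'tf' and 'nes' columns: ", path)
  class(d) <- c("netfactor_activity", "data.frame")
  d
}

#' @rdname read_activity
#' @param activity data frame from [tf_activity()].
#' @export
write_activity <- function(activity, path) {
  d <- as.data.frame(activity)
  for (cn in intersect(c("nes", "p_viper", "fdr_viper"), names(d)))
    d[[cn]] <- fmt_num(d[[cn]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
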