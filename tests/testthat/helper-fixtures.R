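# Shared fixture builders: everything is generated in code at test time.

# small labelled expression matrix with controllable structure
toy_expr <- function(G = 10, n = 24, seed = 1, tf_rows = 2) {
  set.seed(seed)
  ids <- c(sprintf("TF%02d", seq_len(tf_rows)),
           sprintf("G%03d", seq_len(G - tf_rows)))
  m <- matrix(rnorm(G * n), G, n,
              dimnames = list(ids, sprintf("S%03d", seq_len(n))))
  m
}

toy_labels <- function(expr, n_case = ncol(expr) %/% 2) {
  n <- ncol(expr)
  setNames(rep(c("case", "control"), c(n_case, n - n_case)), colnames(expr))
}

# small planted study, cheap enough for unit tests
quick_study <- function(seed = 1) {
  simulate_study(seed = seed, n_tfs = 8, n_genes = 100, regulon_size = 15,
                 n_drivers = 2, overlap_frac = 0.2, n_cases = 40,
                 n_controls = 40, n_from_drivers = 20, n_decoys = 8)
}

# network built directly from named target vectors (unit mi/support)
grn_from_sets <- function(sets, modes = NULL) {
  ed <- do.call(rbind, lapply(names(sets), function(tf) {
    tg <- sets[[tf]]
    data.frame(tf = tf, target = tg,
               mode = if (is.null(modes)) rep(1L, length(tg)) else modes[[tf]],
               stringsAsFactors = FALSE)
  }))
  grn(ed)
}

# exhaustive rational vertex enumeration oracle for
# min sum(x) s.t. t(A) x >= 1, x >= 0 (small instances only)
lp_vertex_oracle <- function(A) {
  t_n <- nrow(A); g_n <- ncol(A)
  C <- rbind(t(A), diag(t_n))        # all constraint normals
  d <- c(rep(1, g_n), rep(0, t_n))   # right-hand sides
  best <- Inf
  for (rows in combn(nrow(C), t_n, simplify = FALSE)) {
    M <- C[rows, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, d[rows]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(x >= -1e-9) && all(t(A) %*% x >= 1 - 1e-9)) {
      best <- min(best, sum(x))
    }
  }
  best
}

# independent hypergeometric upper tail by explicit choose() enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent BH step-up closed form: adj_(i) = min_{j>=i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent plug-in MI oracle from a contingency table of counts
mi_table_oracle <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / n
    if (p > 0) s <- s + p * log(p / (px[i] * py[j]))
  }
  as.numeric(s)
}

# rule-by-rule DPI oracle for a single triangle. Edges: data frame with
# node1, node2, mi. Returns the surviving undirected edge set (as "a|b"
# keys, a < b) after one DPI evaluation.
dpi_triangle_oracle <- function(edges, tfs, tolerance = 0) {
  is_tx <- function(a, b) (a %in% tfs) || (b %in% tfs)
  key <- function(a, b) {
    if ((a %in% tfs) && !(b %in% tfs)) paste(a, b)
    else if (!(a %in% tfs) && (b %in% tfs)) paste(b, a)
    else paste(min(a, b), max(a, b))
  }
  ed <- edges
  ed$tx <- mapply(is_tx, ed$node1, ed$node2)
  ed$key <- mapply(key, ed$node1, ed$node2)
  ord <- order(ed$mi, ed$key, method = "radix")
  ed <- ed[ord, ]
  fire <- if (tolerance <= 0) TRUE else ed$mi[1] < (1 - tolerance) * ed$mi[2]
  if (fire) {
    victim <- 1L
    if (ed$tx[victim] && any(!ed$tx)) victim <- which(!ed$tx)[1]
    ed <- ed[-victim, ]
  }
  sort(unname(mapply(function(a, b) paste(min(a, b), max(a, b), sep = "|"),
                     ed$node1, ed$node2)), method = "radix")
}

# undirected edge keys of an apply_dpi result (TF-TF rows collapse)
dpi_result_keys <- function(d) {
  if (!nrow(d)) return(character(0))
  sort(unique(unname(mapply(function(a, b) paste(min(a, b), max(a, b), sep = "|"),
                            d$tf, d$target))), method = "radix")
}
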