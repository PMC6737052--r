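# Mutual information estimator and the MI map.

test_that("estimate_mi reproduces hand-computed plug-in values", {
  # independent equal-frequency bins: joint table uniform
  expect_equal(estimate_mi(c(1, 2, 3, 4), c(1, 3, 2, 4), n_bins = 2), 0)
  # perfect dependence, diagonal 2x2 table: ln 2
  expect_equal(estimate_mi(1:8, 1:8, n_bins = 2), log(2), tolerance = 1e-12)
  # joint counts [[3,1],[1,3]]
  x <- c(1, 1, 1, 1, 2, 2, 2, 2)
  y <- c(1, 1, 1, 2, 1, 2, 2, 2)
  expect_equal(estimate_mi(x, y, n_bins = 2),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
  expect_equal(estimate_mi(x, y, n_bins = 2),
               mi_table_oracle(matrix(c(3, 1, 1, 3), 2)), tolerance = 1e-12)
})

test_that("estimate_mi input contract: mismatched lengths, constants, bins", {
  expect_error(estimate_mi(1:4, 1:5), class = "netfactor_input_error")
  expect_warning(mi <- estimate_mi(rep(2, 6), 1:6, n_bins = 2), "constant")
  expect_equal(mi, 0)
  expect_error(estimate_mi(1:3, 1:3, n_bins = 4), class = "netfactor_input_error")
  expect_error(estimate_mi(1:6, 1:6, n_bins = 1), class = "netfactor_input_error")
})

test_that("MI is symmetric, non-negative, and maximal on self-dependence", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    nb <- sample(2:5, 1)
    x <- rnorm(n); y <- rnorm(n)
    mxy <- estimate_mi(x, y, nb)
    expect_gte(mxy, 0)
    expect_equal(mxy, estimate_mi(y, x, nb), tolerance = 1e-12)
    expect_gte(estimate_mi(x, x, nb) + 1e-12, mxy)
  }
})

test_that("MI against the direct table oracle on random discretizations", {
  set.seed(12)
  for (r in 1:20) {
    n <- sample(12:40, 1); nb <- sample(2:4, 1)
    x <- rnorm(n); y <- x * runif(1, -1, 1) + rnorm(n)
    B <- netfactor:::bin_rows(rbind(x, y), nb)
    tab <- table(factor(B[1, ], levels = 0:(nb - 1)),
                 factor(B[2, ], levels = 0:(nb - 1)))
    expect_equal(estimate_mi(x, y, nb), mi_table_oracle(unclass(tab)),
                 tolerance = 1e-9)
  }
})

test_that("build_mi_matrix covers TF-involving pairs and is symmetric in storage", {
  X <- toy_expr(G = 3, n = 12, tf_rows = 2)
  m <- build_mi_matrix(X, c("TF01", "TF02"), n_bins = 2)
  expect_equal(nrow(m), 3) # complete graph on 2 TFs + 1 gene
  expect_true(all(m$node1 < m$node2)) # each undirected pair stored once
  # recompute with swapped roles: MI values identical
  m2 <- build_mi_matrix(X, c("TF01", "TF02"), n_bins = 2)
  expect_identical(m, m2)
})

test_that("build_mi_matrix drops absent TFs with a warning, errors when none left", {
  X <- toy_expr(G = 4, n = 10, tf_rows = 1)
  expect_warning(m <- build_mi_matrix(X, c("TF01", "NOPE"), n_bins = 2), "NOPE")
  # every TF-gene pair present (gene-gene triangle closers may appear too)
  tf_rows <- m$node1 == "TF01" | m$node2 == "TF01"
  expect_equal(sum(tf_rows), 3)
  expect_error(suppressWarnings(build_mi_matrix(X, "NOPE", n_bins = 2)),
               class = "netfactor_input_error")
})

test_that("DPI removes the weakest edge of a clique", {
  m <- data.frame(node1 = c("TF1", "TF1", "TF2"),
                  node2 = c("TF2", "g1", "g1"),
                  mi = c(0.5, 0.4, 0.3))
  out <- apply_dpi(m, c("TF1", "TF2"))
  expect_setequal(dpi_result_keys(out), c("TF1|TF2", "TF1|g1"))
})

test_that("DPI exception removes the non-transcriptional edge instead", {
  m <- data.frame(node1 = c("TF1", "TF1", "g1"),
                  node2 = c("g1", "g2", "g2"),
                  mi = c(0.2, 0.4, 0.6))
  out <- apply_dpi(m, "TF1")
  expect_setequal(dpi_result_keys(out), c("TF1|g1", "TF1|g2"))
})

test_that("DPI leaves triangle-free networks unchanged (TF edges)", {
  m <- data.frame(node1 = c("TF1", "TF1", "TF2"),
                  node2 = c("g1", "g2", "g3"),
                  mi = c(0.2, 0.3, 0.4))
  out <- apply_dpi(m, c("TF1", "TF2"))
  expect_setequal(dpi_result_keys(out), c("TF1|g1", "TF1|g2", "TF2|g3"))
})

test_that("DPI matches the rule-by-rule oracle on enumerated triangles", {
  tf_patterns <- list(c("A", "B", "C"), c("A", "B"), "A")
  mi_sets <- list(c(0.5, 0.4, 0.3), c(0.3, 0.4, 0.5), c(0.4, 0.5, 0.3),
                  c(0.4, 0.4, 0.5), c(0.5, 0.4, 0.4), c(0.4, 0.4, 0.4),
                  c(0.1, 0.9, 0.5))
  for (tfs in tf_patterns) {
    for (mi in mi_sets) {
      ed <- data.frame(node1 = c("A", "A", "B"), node2 = c("B", "C", "C"),
                       mi = mi)
      got <- dpi_result_keys(apply_dpi(ed, tfs))
      want <- dpi_triangle_oracle(ed, tfs)
      # apply_dpi reports only transcriptional edges
      keep_tx <- vapply(strsplit(want, "|", fixed = TRUE),
                        function(p) any(p %in% tfs), logical(1))
      expect_identical(got, want[keep_tx],
                       info = paste("tfs:", paste(tfs, collapse = ","),
                                    "mi:", paste(mi, collapse = ",")))
    }
  }
})

test_that("DPI tolerance keeps near-ties; max edge survives unless non-transcriptional", {
  ed <- data.frame(node1 = c("A", "A", "B"), node2 = c("B", "C", "C"),
                   mi = c(0.40, 0.41, 0.5))
  # min is within 5% of second: kept at tolerance 0.05, removed at 0
  out_tol <- apply_dpi(ed, c("A", "B"), tolerance = 0.05)
  expect_setequal(dpi_result_keys(out_tol), c("A|B", "A|C", "B|C"))
  out0 <- apply_dpi(ed, c("A", "B"))
  expect_length(dpi_result_keys(out0), 2)
  # property: strict-max edge never removed at tolerance 0 unless non-TF edge
  set.seed(13)
  for (r in 1:30) {
    mi <- sort(runif(3), decreasing = FALSE)
    tfs <- sample(list(c("A", "B", "C"), c("A", "B")), 1)[[1]]
    ed$mi <- sample(mi)
    out <- apply_dpi(ed, tfs)
    mx <- ed[which.max(ed$mi), ]
    if ((mx$node1 %in% tfs) || (mx$node2 %in% tfs)) {
      expect_true(paste(pmin(mx$node1, mx$node2), pmax(mx$node1, mx$node2),
                        sep = "|") %in% dpi_result_keys(out))
    }
  }
})

test_that("gene-gene edges are inert for the surviving TF edge set", {
  # consensus fast path (gene_pairs = FALSE) must give identical TF edges
  set.seed(14)
  for (r in 1:10) {
    X <- toy_expr(G = 14, n = 30, seed = 100 + r, tf_rows = 3)
    X[4, ] <- X[1, ] * 0.9 + rnorm(30, sd = 0.4)
    X[5, ] <- X[1, ] * 0.7 + rnorm(30, sd = 0.4)
    X[6, ] <- X[2, ] * 0.8 + rnorm(30, sd = 0.4)
    tfs <- c("TF01", "TF02", "TF03")
    thr <- 0.03
    full <- apply_dpi(build_mi_matrix(X, tfs, 3, thr, gene_pairs = TRUE), tfs)
    fast <- apply_dpi(build_mi_matrix(X, tfs, 3, thr, gene_pairs = FALSE), tfs)
    expect_identical(full[c("tf", "target", "mi")],
                     fast[c("tf", "target", "mi")])
  }
})
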