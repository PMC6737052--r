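# Coverage matrix, L1-relaxed set cover, ranking, selection filter, greedy
# baseline and coverage curves.

mk_activity <- function(tfs, fdr) {
  data.frame(tf = tfs, nes = 1, p_viper = fdr, fdr_viper = fdr,
             stringsAsFactors = FALSE)
}
mk_enrichment <- function(tfs, fdr, overlap = 1) {
  data.frame(tf = tfs, regulon_size = 5, overlap = overlap, p_fisher = fdr,
             fdr_biomarker = fdr, stringsAsFactors = FALSE)
}

test_that("coverage matrix entries are the dual-FDR likelihood product", {
  g <- grn_from_sets(list(TF1 = c("a", "b"), TF2 = c("b", "c")))
  act <- mk_activity(c("TF1", "TF2"), c(0.0151, 0))
  enr <- mk_enrichment(c("TF1", "TF2"), c(0.006, 0))
  A <- build_coverage_matrix(g, act, enr, c("a", "b", "c"))
  # the printed dual-FDR pair (0.0151, 0.006) gives 0.9849 * 0.994
  expect_equal(A["TF1", "a"], 0.9849 * 0.994, tolerance = 1e-9)
  expect_equal(A["TF1", "a"], 0.97899, tolerance = 1e-4)
  expect_equal(A["TF2", "c"], 1) # both FDRs zero
  expect_equal(A["TF1", "c"], 0) # not a target
  expect_length(attr(A, "uncovered"), 0)
})

test_that("coverage matrix drops NA-activity rows and uncoverable columns", {
  g <- grn_from_sets(list(TF1 = c("a", "b"), TF2 = c("b", "c")))
  act <- mk_activity(c("TF1", "TF2"), c(0.1, NA))
  enr <- mk_enrichment(c("TF1", "TF2"), c(0.1, 0.1))
  expect_warning(A <- build_coverage_matrix(g, act, enr, c("a", "c", "z")),
                 "NA activity")
  expect_equal(rownames(A), "TF1")
  expect_equal(colnames(A), "a") # c covered only by dropped TF2, z absent
  expect_setequal(attr(A, "uncovered"), c("c", "z"))
  expect_error(suppressWarnings(
    build_coverage_matrix(g, act, enr, "z")), class = "netfactor_input_error")
})

test_that("set-cover LP reproduces the analytic two-TF solution", {
  A <- rbind(TF1 = c(g1 = 0.9, g2 = 0.9, g3 = 0),
             TF2 = c(g1 = 0, g2 = 0.8, g3 = 0.8))
  s <- solve_l1_cover(A)
  expect_equal(unname(s$weights), c(10 / 9, 5 / 4), tolerance = 1e-8)
  expect_equal(s$objective, 10 / 9 + 5 / 4, tolerance = 1e-8)
  # single TF covering everything at entry 1
  expect_equal(unname(solve_l1_cover(matrix(1, 1, 3,
    dimnames = list("T", c("a", "b", "c"))))$weights), 1)
})

test_that("duplicated regulons are canonicalized deterministically", {
  A <- matrix(0.5, 2, 2, dimnames = list(c("TFa", "TFb"), c("g1", "g2")))
  s <- solve_l1_cover(A)
  expect_equal(s$objective, 2, tolerance = 1e-8)
  expect_equal(unname(s$weights), c(2, 0), tolerance = 1e-8)
})

test_that("LP optimum matches exhaustive vertex enumeration on random instances", {
  set.seed(41)
  n_done <- 0
  while (n_done < 60) {
    t_n <- sample(2:6, 1); g_n <- sample(2:8, 1)
    A <- matrix(round(runif(t_n * g_n), 3) * (runif(t_n * g_n) < 0.6),
                t_n, g_n)
    if (any(colSums(A > 0) == 0)) next
    dimnames(A) <- list(paste0("t", seq_len(t_n)), paste0("g", seq_len(g_n)))
    s <- solve_l1_cover(A)
    expect_equal(s$objective, lp_vertex_oracle(A), tolerance = 1e-8)
    expect_gte(min(t(A) %*% s$weights), 1 - 1e-6)
    n_done <- n_done + 1
  }
})

test_that("scaling the coverage matrix rescales the objective and keeps the ranking", {
  set.seed(42)
  A <- matrix(runif(24) * (runif(24) < 0.7), 4, 6,
              dimnames = list(paste0("t", 1:4), paste0("g", 1:6)))
  A[1, colSums(A > 0) == 0] <- 0.5
  s1 <- solve_l1_cover(A)
  act <- mk_activity(rownames(A), c(0.01, 0.02, 0.03, 0.04))
  enr <- mk_enrichment(rownames(A), c(0.01, 0.02, 0.03, 0.04))
  r1 <- rank_regulators(s1$weights, act, enr)
  for (cc in c(0.5, 0.2)) {
    s2 <- solve_l1_cover(A * cc)
    expect_equal(s2$objective, s1$objective / cc, tolerance = 1e-7)
    r2 <- rank_regulators(s2$weights, act, enr)
    expect_identical(r2$tf, r1$tf)
  }
})

test_that("greedy baseline orders by static counts with lexicographic ties", {
  g <- grn_from_sets(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                          C = "g5"))
  gr <- greedy_cover(g, paste0("g", 1:5))
  expect_equal(gr$order, c("A", "B", "C"))
  expect_equal(gr$curve, c(3, 4, 5))
  # single TF
  g1 <- grn_from_sets(list(A = c("g1", "g2")))
  expect_equal(greedy_cover(g1, c("g1", "g2", "g9"))$curve, 2)
  # equal counts resolve alphabetically
  ge <- grn_from_sets(list(B = "g1", A = "g2"))
  expect_equal(greedy_cover(ge, c("g1", "g2"))$order, c("A", "B"))
})

test_that("ranking is by weight with FDR-product and lexicographic tie-breaks", {
  act <- mk_activity(c("A", "B", "C"), c(0.1, 0.01, 0.1))
  enr <- mk_enrichment(c("A", "B", "C"), c(0.1, 0.1, 0.1))
  r <- rank_regulators(c(A = 1.07, B = 1.02, C = 0), act, enr)
  expect_equal(r$tf, c("A", "B", "C"))
  expect_equal(r$rank, 1:3)
  # equal weights: smaller fdr product first
  r2 <- rank_regulators(c(A = 1, B = 1), act, enr)
  expect_equal(r2$tf, c("B", "A"))
})

test_that("dual-FDR selection mirrors the published accept/reject patterns", {
  tfs <- c("ETV4like", "GTF2A2like", "Zero")
  act <- mk_activity(tfs, c(0.0324, 0.0113, 0.01))
  enr <- mk_enrichment(tfs, c(0.00007, 0.3951, 0.01))
  ranking <- rank_regulators(c(ETV4like = 1.015, GTF2A2like = 1.014, Zero = 0),
                             act, enr)
  sel <- significant_set(ranking, act, enr)
  expect_true("ETV4like" %in% sel)     # both FDRs <= 0.05
  expect_false("GTF2A2like" %in% sel)  # fails FDR_BIOMARKER
  expect_false("Zero" %in% sel)        # zero weight
})

test_that("coverage curves accumulate distinct biomarker genes", {
  bm <- paste0("g", 1:30)
  g <- grn_from_sets(list(A = bm[1:16], B = bm[17:24]))
  expect_equal(coverage_curve(c("A", "B"), g, bm), c(16, 24))
  # overlapping by 7: 16 + 15 - 7
  g2 <- grn_from_sets(list(A = bm[1:16], B = bm[10:24]))
  expect_equal(coverage_curve(c("A", "B"), g2, bm), c(16, 24))
  g3 <- grn_from_sets(list(A = bm[1:5], B = bm[1:5]))
  expect_equal(coverage_curve(c("A", "B"), g3, bm), c(5, 5))
  expect_true(all(diff(coverage_curve(c("A", "B"), g2, bm)) >= 0))
})

test_that("weight-ranked coverage beats greedy on redundant high-entry instances", {
  # drivers share most targets (redundant); weak TFs cover few genes each.
  # all entries high so the LP is not distorted by near-zero likelihoods.
  bm <- paste0("g", 1:20)
  sets <- list(D1 = bm[1:12],                 # 12 biomarker targets
               D2 = bm[c(1:10, 13, 14)],     # redundant with D1 (counts tie)
               U1 = bm[13:20])               # complements D1 non-redundantly
  g <- grn_from_sets(sets)
  tfs <- names(sets)
  act <- mk_activity(tfs, rep(0.01, 3))
  enr <- mk_enrichment(tfs, rep(0.01, 3))
  A <- build_coverage_matrix(g, act, enr, bm)
  s <- solve_l1_cover(A)
  expect_lt(s$weights["D2"], 1e-6) # LP sees the redundancy, greedy does not
  ranking <- rank_regulators(s$weights, act, enr)
  lasso_curve <- coverage_curve(ranking$tf, g, bm)
  greedy <- greedy_cover(g, bm)
  expect_equal(greedy$order, c("D1", "D2", "U1"))
  expect_true(all(lasso_curve >= greedy$curve))
  expect_gt(lasso_curve[2], greedy$curve[2]) # strictly better mid-curve
  expect_true(all(diff(lasso_curve) >= 0))
  expect_equal(max(lasso_curve), max(greedy$curve))
})
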