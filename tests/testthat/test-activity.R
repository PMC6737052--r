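# Differential-expression signature, normal scores, enrichment score and
# the permutation null.

test_that("Welch signature matches the hand formula and its symmetries", {
  X <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(X) <- paste0("s", 1:6)
  lab <- setNames(rep(c("case", "control"), each = 3), colnames(X))
  X <- rbind(X, g2 = c(4, 5, 6, 1, 2, 3))
  sig <- compute_signature(X, lab)
  expect_equal(unname(sig["g1"]), (2 - 5) / sqrt(1 / 3 + 1 / 3),
               tolerance = 1e-12)
  # swapping labels negates every statistic
  lab_sw <- setNames(ifelse(lab == "case", "control", "case"), names(lab))
  expect_equal(compute_signature(X, lab_sw), -sig, tolerance = 1e-12)
  # identical group values give 0 with a warning
  Xc <- rbind(g1 = rep(2, 6)); colnames(Xc) <- names(lab)
  Xc <- rbind(Xc, g2 = 1:6)
  expect_warning(sc <- compute_signature(Xc, lab), "zero pooled variance")
  expect_equal(unname(sc["g1"]), 0)
  # class-size contract
  expect_error(compute_signature(X, setNames(c("case", rep("control", 5)),
                                             colnames(X))),
               class = "netfactor_input_error")
})

test_that("rank-sum signature agrees with wilcox.test normal approximation", {
  set.seed(21)
  X <- toy_expr(G = 6, n = 20)
  lab <- toy_labels(X)
  sig <- compute_signature(X, lab, method = "signed_rank_z")
  g <- rownames(X)[3]
  w <- wilcox.test(X[g, lab == "case"], X[g, lab == "control"],
                   exact = FALSE, correct = FALSE)
  z_ref <- qnorm(w$p.value / 2, lower.tail = FALSE) * sign(sig[g])
  expect_equal(abs(unname(sig[g])), abs(unname(z_ref)), tolerance = 1e-6)
})

test_that("normal scores are the qnorm(rank/(G+1)) transform", {
  sig <- setNames(c(0.3, -1, 2, 0.1, -0.5), paste0("g", 1:5))
  z <- normal_scores(sig)
  expect_equal(unname(z["g3"]), qnorm(5 / 6), tolerance = 1e-9) # top of G=5
  expect_equal(unname(z["g4"]), 0) # median of odd G (value 0.1)
  expect_equal(normal_scores(-sig), -z, tolerance = 1e-12)
  expect_identical(order(z), order(sig)) # order-preserving
})

test_that("enrichment score: single-target, sign flip, symmetric cancellation", {
  sig <- setNames(c(0.3, -1, 2, 0.1, -0.5), paste0("g", 1:5))
  top <- data.frame(target = "g3", mode = 1L)
  expect_equal(nes_score(sig, top), qnorm(5 / 6), tolerance = 1e-9)
  expect_equal(nes_score(sig, transform(top, mode = -1L)), -qnorm(5 / 6),
               tolerance = 1e-9)
  sym <- data.frame(target = c("g3", "g2"), mode = c(1L, 1L)) # ranks 5 and 1
  expect_equal(nes_score(sig, sym), 0, tolerance = 1e-12)
  # empty effective regulon is NA
  expect_true(is.na(nes_score(sig, data.frame(target = "g9", mode = 1L))))
  expect_true(is.na(nes_score(sig, data.frame(target = "g3", mode = 0L))))
})

test_that("random-regulon enrichment scores have mean ~0 and variance ~1", {
  set.seed(22)
  G <- 400
  sig <- setNames(rnorm(G), paste0("g", 1:G))
  m <- 25
  draws <- replicate(400, {
    nes_score(sig, data.frame(target = sample(names(sig), m),
                              mode = sample(c(-1L, 1L), m, TRUE)))
  })
  se_mean <- 1 / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se_mean)
  se_var <- sqrt(2 / (length(draws) - 1))
  expect_lt(abs(var(draws) - 1), 3 * se_var)
})

test_that("permutation p-values respect the add-one bound and gene-null invariance", {
  st <- quick_study(seed = 6)
  g <- grn_from_truth(st$truth)
  regs <- regulons(g)
  nul <- permutation_null(st$expr, st$labels, regs, n_perm = 50, seed = 3)
  expect_true(all(nul$p >= 1 / 51 - 1e-12, na.rm = TRUE))
  expect_true(all(nul$p <= 1, na.rm = TRUE))
  # regulon = all signature genes with uniform mode: gene-permutation
  # cannot change the score, p must be 1
  all_genes <- list(ALL = data.frame(target = rownames(st$expr), mode = 1L))
  nul_g <- permutation_null(st$expr, st$labels, all_genes,
                            null_model = "genes", n_perm = 50, seed = 3)
  expect_equal(unname(nul_g$p["ALL"]), 1)
})

test_that("small cohorts enumerate all distinct label permutations", {
  st <- quick_study(seed = 7)
  X <- st$expr[, c(1:3, 41:43)]
  lab <- st$labels[c(1:3, 41:43)]
  regs <- regulons(grn_from_truth(st$truth))[1:2]
  expect_warning(
    nul <- permutation_null(X, lab, regs, n_perm = 30, seed = 1),
    "distinct label permutations")
  expect_equal(nul$n_perm_used, choose(6, 3))
})

test_that("tf_activity: single-TF BH identity and label-swap antisymmetry", {
  st <- quick_study(seed = 8)
  g <- grn_from_truth(st$truth)
  g1 <- grn(g$edges[g$edges$tf == "TF01", ], tfs = "TF01")
  act1 <- tf_activity(st$expr, st$labels, g1, n_perm = 100, seed = 5)
  expect_equal(act1$fdr_viper, act1$p_viper)
  act <- tf_activity(st$expr, st$labels, g, n_perm = 100, seed = 5)
  lab_sw <- setNames(ifelse(st$labels == "case", "control", "case"),
                     names(st$labels))
  act_sw <- tf_activity(st$expr, lab_sw, g, n_perm = 100, seed = 5)
  expect_equal(act_sw$nes, -act$nes, tolerance = 1e-9)
  expect_equal(act_sw$p_viper, act$p_viper, tolerance = 1e-12)
  # BH monotonicity in p rank order
  o <- order(act$p_viper)
  expect_true(all(diff(act$fdr_viper[o]) >= -1e-12))
})

test_that("planted drivers get the smallest activity FDRs", {
  hits <- 0L
  for (s in 1:6) {
    st <- quick_study(seed = 30 + s)
    g <- grn_from_truth(st$truth)
    act <- tf_activity(st$expr, st$labels, g, n_perm = 200, seed = s)
    top2 <- act$tf[order(act$fdr_viper, act$p_viper)][1:2]
    if (setequal(top2, st$truth$drivers)) hits <- hits + 1L
  }
  expect_gte(hits, 5)
})

test_that("activity table round-trips through TSV", {
  act <- data.frame(tf = c("A", "B"), nes = c(1.5, NA),
                    p_viper = c(0.01, NA), fdr_viper = c(0.02, NA),
                    stringsAsFactors = FALSE)
  class(act) <- c("netfactor_activity", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity(act, path)
  act2 <- read_activity(path)
  expect_equal(act2$nes, c(1.5, NA))
  expect_equal(act2$fdr_viper, c(0.02, NA))
})
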