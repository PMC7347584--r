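test_that("benjamini_hochberg matches the hand-computed step-up and oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_error(benjamini_hochberg(c(0.5, 1.1)), "\\[0, 1\\]")

  # brute-force min-over-tail oracle on random vectors; classic step-up
  # rejection set at 0.05 must coincide with thresholding the adjusted values
  set.seed(42)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_bruteforce(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
    o <- order(p); m <- 50
    k <- suppressWarnings(max(which(p[o] <= 0.05 * seq_len(m) / m)))
    stepup <- if (is.finite(k)) o[seq_len(k)] else integer(0)
    expect_setequal(which(adj <= 0.05), stepup)
  }
})

test_that("de_test: design guard, null control, sensitivity, monotonicity", {
  em_small <- gen_expression_matrix(expr_sim_config(n_genes = 50,
                                                    n_per_group = 2, seed = 1))
  expect_error(de_test(em_small), class = "cryofx_design_error")

  em <- gen_expression_matrix(expr_sim_config(n_genes = 800, n_per_group = 6,
                                              de_fraction = 0.1,
                                              log2fc_magnitude = 2, seed = 12))
  truth <- attr(em, "truth")
  res <- de_test(em)
  expect_gt(mean(res$fdr[truth$is_de] <= 0.05), 0.7)
  expect_identical(res$direction, ifelse(res$log2fc >= 0, "up", "down"))
  # recovered fold changes agree in sign with the simulated ones
  called <- truth$is_de & res$fdr <= 0.05
  expect_gt(mean(sign(res$log2fc[called]) == sign(truth$true_log2fc[called])),
            0.95)

  # duplicating every sample strengthens evidence for every true DE gene
  em3 <- gen_expression_matrix(expr_sim_config(n_genes = 300, n_per_group = 6,
                                               de_fraction = 0.1,
                                               log2fc_magnitude = 3, seed = 21))
  tr3 <- attr(em3, "truth")
  cts <- cbind(em3$counts, em3$counts)
  colnames(cts) <- c(colnames(em3$counts), paste0(colnames(em3$counts), "_d"))
  em3d <- expression_matrix(cts, setNames(rep(em3$group_of, 2), colnames(cts)))
  p1 <- de_test(em3)$p_value; p2 <- de_test(em3d)$p_value
  expect_true(all(p2[tr3$is_de] <= p1[tr3$is_de] + 1e-12))
})

test_that("de_test ranks genes like the established edgeR exact test", {
  # independent oracle from ENVIRONMENT: edgeR on the same fixture
  suppressPackageStartupMessages(requireNamespace("edgeR"))
  em <- gen_expression_matrix(expr_sim_config(n_genes = 500, n_per_group = 5,
                                              de_fraction = 0.1,
                                              log2fc_magnitude = 2, seed = 33))
  mine <- de_test(em)
  y <- edgeR::DGEList(counts = em$counts, group = factor(em$group_of))
  y <- edgeR::estimateDisp(edgeR::calcNormFactors(y))
  et <- edgeR::exactTest(y)$table
  expect_gt(cor(log10(mine$p_value + 1e-300),
                log10(et$PValue + 1e-300), method = "spearman"), 0.85)
})

test_that("variability post-filter reproduces the hand-enumerated fixtures", {
  cand <- data.frame(gene_id = "g1", log2fc = 2, p_value = 0.001,
                     fdr = 0.01, direction = "up")

  # fixture 1: kept (two qualifying VT samples, requirement = 2)
  em1 <- make_fpkm_fixture(c(1, 1, 1, 1), c(0.5, 0.5, 30, 40))
  f1 <- variability_postfilter(em1, cand)
  expect_gt(f1$trace$cv_percent, 50)
  expect_gt(f1$trace$mean_median_gap, 1)
  expect_true(f1$trace$triggered)
  expect_identical(f1$trace$n_qualifying_samples, 2L)
  expect_identical(f1$trace$required, 2L)
  expect_true(f1$trace$kept)
  expect_equal(nrow(f1$kept), 1)

  # fixture 2: dropped (single qualifying sample)
  em2 <- make_fpkm_fixture(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 40))
  f2 <- variability_postfilter(em2, cand)
  expect_true(f2$trace$triggered)
  expect_identical(f2$trace$n_qualifying_samples, 1L)
  expect_false(f2$trace$kept)
  expect_equal(nrow(f2$kept), 0)

  # low CV bypasses the filter regardless of group pattern
  em3 <- make_fpkm_fixture(c(10, 10.5, 9.5, 10), c(30, 29, 31, 30))
  f3 <- variability_postfilter(em3, cand)
  expect_false(f3$trace$triggered)
  expect_true(f3$trace$kept)

  # zero expression in both groups: dropped with flag
  em4 <- make_fpkm_fixture(rep(0, 4), rep(0, 4))
  f4 <- variability_postfilter(em4, cand)
  expect_true(f4$trace$zero_expression)
  expect_false(f4$trace$kept)
})

test_that("filter only triggers on the CV AND gap conjunction", {
  cand <- data.frame(gene_id = "g1", log2fc = 1, p_value = 0.01,
                     fdr = 0.02, direction = "up")
  # high CV but tiny FPKM scale -> gap below 1 -> no trigger
  em <- make_fpkm_fixture(c(0.01, 0.01, 0.01, 0.01), c(0.005, 0.005, 0.3, 0.4))
  tr <- variability_postfilter(em, cand)$trace
  expect_gt(tr$cv_percent, 50)
  expect_lt(tr$mean_median_gap, 1)
  expect_false(tr$triggered)
  expect_true(tr$kept)
})

test_that("call_dets composes test, FDR cut and filter; order invariant", {
  em <- gen_expression_matrix(expr_sim_config(n_genes = 600, n_per_group = 6,
                                              de_fraction = 100 / 600,
                                              log2fc_magnitude = 3, seed = 14))
  truth <- attr(em, "truth")
  dets <- call_dets(em)
  expect_gt(sum(dets$gene_id %in% truth$gene_id[truth$is_de]),
            sum(truth$is_de) / 2)

  # permuting sample columns and gene rows leaves the DET set unchanged
  perm_s <- sample(ncol(em$counts)); perm_g <- sample(nrow(em$counts))
  em_p <- expression_matrix(em$counts[perm_g, perm_s],
                            em$group_of[colnames(em$counts)[perm_s]])
  dets_p <- call_dets(em_p)
  expect_setequal(dets$gene_id, dets_p$gene_id)

  # null matrix: near-empty DET list
  rates <- vapply(1:5, function(s) {
    emn <- gen_expression_matrix(expr_sim_config(n_genes = 500, n_per_group = 6,
                                                 de_fraction = 0, seed = s + 100))
    nrow(call_dets(emn)) / 500
  }, 1)
  expect_lt(mean(rates), 0.02)
})
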