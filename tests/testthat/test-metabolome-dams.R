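test_that("internal-standard normalisation: scaling laws and hand fixture", {
  x <- matrix(c(10, 2, 20, 4, 30, 6, 12, 2, 40, 8, 50, 10), nrow = 2,
              dimnames = list(c("m", "std"),
                              c("NC_1", "NC_2", "NC_3", "VT_1", "VT_2", "VT_3")))
  mt <- make_metab_fixture(x, standards = "std")
  norm <- normalize_internal_standard(mt)
  expect_equal(unname(norm$intensities["m", ]), c(5, 5, 5, 6, 5, 5))
  expect_false("std" %in% norm$metabolite_ids)

  # uniform standard c: output = input / c
  x2 <- x; x2["std", ] <- 4
  n2 <- normalize_internal_standard(make_metab_fixture(x2, standards = "std"))
  expect_equal(n2$intensities["m", ], x["m", ] / 4)

  # doubling one sample's raw column (standard included) changes nothing
  x3 <- x; x3[, "VT_2"] <- 2 * x3[, "VT_2"]
  n3 <- normalize_internal_standard(make_metab_fixture(x3, standards = "std"))
  expect_equal(n3$intensities, norm$intensities)

  # idempotence: re-normalising with a unit standard is the identity
  x4 <- rbind(norm$intensities, std = 1)
  n4 <- normalize_internal_standard(make_metab_fixture(x4, standards = "std"))
  expect_equal(n4$intensities, norm$intensities)
})

test_that("normalisation errors: no standard for a fraction, duplicates", {
  x <- matrix(runif(6, 1, 2), 2, 3,
              dimnames = list(c("a", "b"), c("NC_1", "NC_2", "VT_1")))
  expect_error(normalize_internal_standard(make_metab_fixture(x)),
               class = "cryofx_config_error")
  mt2 <- make_metab_fixture(x, standards = c("a", "b"))
  expect_error(normalize_internal_standard(mt2), "more than one")
})

test_that("anova_oneway: identities and hand-computed fixture", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- anova_oneway(g)
  expect_equal(a$F, 3.0)
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))
  # independent oracle: base R one-way ANOVA
  df <- data.frame(y = unlist(g), grp = factor(rep(1:3, each = 3)))
  expect_equal(a$p, anova(aov(y ~ grp, df))[1, "Pr(>F)"])

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # F = t^2 identity at k = 2 (p identical to pooled two-sided t-test)
  set.seed(5)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  a2 <- anova_oneway(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_lt(abs(a2$F - tt$statistic^2), 1e-10)
  expect_lt(abs(a2$p - tt$p.value), 1e-10)

  degen <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(degen$p, 1)
  expect_true(attr(degen, "degenerate"))
  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(1, 1:3)), ">= 2 values")
})

test_that("tukey_hsd: t-test identity at k = 2, ties, separation, aov oracle", {
  set.seed(6)
  x <- rnorm(6); y <- rnorm(6, 1)
  p_tukey <- tukey_hsd(list(a = x, b = y))[["a-b"]]
  p_t <- t.test(x, y, var.equal = TRUE)$p.value
  expect_lt(abs(p_tukey - p_t), 1e-6)

  expect_equal(unname(tukey_hsd(list(c(1, 2), c(1, 2), c(1, 2)))), rep(1, 3))

  far <- tukey_hsd(list(a = rnorm(5), b = rnorm(5), c = rnorm(5, 500)))
  expect_lt(far[["a-c"]], 1e-6)
  expect_lt(far[["b-c"]], 1e-6)

  # independent oracle: stats::TukeyHSD on a balanced random dataset
  set.seed(9)
  df <- data.frame(y = rnorm(15, rep(c(0, 1, 2), each = 5)),
                   grp = factor(rep(c("a", "b", "c"), each = 5)))
  ref <- TukeyHSD(aov(y ~ grp, df))$grp[, "p adj"]
  mine <- tukey_hsd(split(df$y, df$grp))
  expect_lt(abs(mine[["a-b"]] - ref[["b-a"]]), 1e-6)
  expect_lt(abs(mine[["a-c"]] - ref[["c-a"]]), 1e-6)
  expect_lt(abs(mine[["b-c"]] - ref[["c-b"]]), 1e-6)
})

test_that("call_dams: type-I error, sign recovery, label-swap antisymmetry", {
  # null generator: raw p < 0.05 rate ~5% in expectation (mean over seeds;
  # per-table rates are skewed by the shared internal-standard draws)
  rates <- vapply(1:20, function(s) {
    m <- gen_metabolite_table(metab_sim_config(dam_fraction = 0, seed = s))
    mean(call_dams(normalize_internal_standard(m), "F1")$is_dam)
  }, 1)
  expect_lt(abs(mean(rates) - 0.05), 0.03)

  # strong DAMs: recovered log2fc sign matches truth for > 90% of calls
  cfg <- metab_sim_config(dam_fraction = 0.3,
                          fraction_log2fc_mean = c("semi-polar" = 1,
                                                   "non-polar" = -1),
                          noise_cv = 0.2, seed = 3)
  mt <- gen_metabolite_table(cfg)
  truth <- attr(mt, "truth")
  d <- call_dams(normalize_internal_standard(mt), "F1")
  called_true <- d$is_dam & truth$is_dam[match(d$metabolite_id,
                                               truth$metabolite_id)]
  expect_gt(sum(called_true), 20)
  tl <- truth$true_log2fc[match(d$metabolite_id[called_true],
                                truth$metabolite_id)]
  expect_gt(mean(sign(d$log2fc[called_true]) == sign(tl)), 0.9)

  # swapping every sample's group flips log2fc and preserves p
  swapped <- mt
  swapped$group_of[] <- ifelse(mt$group_of == "NC", "VT", "NC")
  d2 <- call_dams(normalize_internal_standard(swapped), "F1")
  expect_equal(d2$log2fc, -d$log2fc)
  expect_equal(d2$p_value, d$p_value)

  # un-normalised table is refused
  expect_error(call_dams(mt, "F1"), class = "cryofx_config_error")
})

test_that("call_dams averages technical replicates before testing", {
  x <- matrix(c(10, 10, 20, 20, 30, 30, 40, 40, 50, 50, 60, 60), nrow = 1,
              dimnames = list("m", c("NC_1a", "NC_1b", "NC_2a", "NC_2b",
                                     "NC_3a", "NC_3b", "VT_1a", "VT_1b",
                                     "VT_2a", "VT_2b", "VT_3a", "VT_3b")))
  mt <- make_metab_fixture(x)
  reps <- setNames(sub("[ab]$", "", colnames(x)), colnames(x))
  d <- call_dams(mt, "F1", tech_rep_of = reps)
  # averaged design: NC {10,20,30}, VT {40,50,60}
  ref <- anova_oneway(list(c(10, 20, 30), c(40, 50, 60)))
  expect_equal(d$p_value, ref$p)
  expect_equal(d$log2fc, log2(50 / 20))
})

test_that("fraction_fold_change_summary: means, invariances, scales", {
  dams <- data.frame(metabolite_id = c("a", "b", "c"),
                     fraction = c("semi-polar", "semi-polar", "non-polar"),
                     log2fc = c(1, -1, 0.5), p_value = 0.01, is_dam = TRUE)
  s <- fraction_fold_change_summary(dams)
  expect_equal(s[["semi-polar"]], 0)
  expect_equal(s[["non-polar"]], 0.5)
  # singleton mean; non-DAM rows ignored; empty result
  dams$is_dam <- c(TRUE, FALSE, FALSE)
  expect_equal(fraction_fold_change_summary(dams),
               c("semi-polar" = 1))
  dams$is_dam <- FALSE
  expect_length(fraction_fold_change_summary(dams), 0)
  # permutation invariance and ratio scale
  dams$is_dam <- TRUE
  sh <- fraction_fold_change_summary(dams[c(3, 1, 2), ])
  expect_equal(sh, s)
  expect_equal(fraction_fold_change_summary(dams, scale = "ratio")[["non-polar"]],
               2^0.5)
})
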