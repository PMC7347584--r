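# Gibbs sampler, posterior summaries and the relevance rule. The analytic
# oracle throughout is the closed-form flat-prior posterior of the contrast
# (location-scale t, see helper-fixtures.R).

test_that("Gibbs matches the analytic flat-prior posterior (n = 20/group)", {
  tab <- make_trait_table(20, delta = 1, sd = 1, seed = 7)
  an <- analytic_contrast_posterior(tab)
  ch <- fit_two_group_model(tab, "x", "F1",
                            config = gibbs_config(n_iter = 160000,
                                                  burn_in = 10000, seed = 3))
  s <- summarize_posterior(ch)
  expect_lt(abs(s$D_mean - an$center), 3 * s$mcse)
  expect_lt(abs(s$P0 - pt(abs(an$center) / an$scale, an$df)), 0.01)
  lim <- qt(0.975, an$df) * an$scale
  expect_lt(abs(s$hpd_low - (an$center - lim)), 0.05 * an$scale)
  expect_lt(abs(s$hpd_high - (an$center + lim)), 0.05 * an$scale)
})

test_that("chains are reproducible and respect thinning bookkeeping", {
  tab <- make_trait_table(10, delta = 0.3, seed = 2)
  cfg <- gibbs_config(n_iter = 5000, burn_in = 500, thin = 3, seed = 9)
  c1 <- fit_two_group_model(tab, "x", "F1", config = cfg)
  c2 <- fit_two_group_model(tab, "x", "F1", config = cfg)
  expect_identical(c1$samples_D, c2$samples_D)
  expect_identical(c1$samples_sigma2, c2$samples_sigma2)
  expect_length(c1$samples_D, (5000 - 500) %/% 3)
  # default protocol: (60000 - 10000) / 10 = 5000 saved draws
  expect_identical((gibbs_config()$n_iter - gibbs_config()$burn_in) %/%
                     gibbs_config()$thin, 5000L)
})

test_that("label swap negates the contrast (antisymmetry)", {
  tab <- make_trait_table(15, delta = 0.8, seed = 4)
  swapped <- tab
  swapped$group <- ifelse(tab$group == "NC", "VT", "NC")
  cfg <- gibbs_config(n_iter = 30000, burn_in = 5000, seed = 6)
  s1 <- summarize_posterior(fit_two_group_model(tab, "x", "F1", config = cfg))
  s2 <- summarize_posterior(fit_two_group_model(swapped, "x", "F1", config = cfg))
  expect_lt(abs(s1$D_mean + s2$D_mean), 3 * (s1$mcse + s2$mcse))
})

test_that("covariate model recovers a nonzero organ/body-weight slope", {
  cfg <- pheno_sim_config(
    n_per_group_per_generation = 40,
    trait_means = c(liver = 110), trait_sds = c(liver = 8),
    group_deltas = list(liver = c(F1 = 6)),
    covariate_slope = 0.025, covariate_traits = "liver",
    generations = "F1", seed = 21)
  tab <- gen_phenotype_table(cfg)
  ch <- fit_two_group_model(tab, "liver", "F1", use_covariate = TRUE,
                            config = gibbs_config(n_iter = 30000,
                                                  burn_in = 5000, seed = 2))
  expect_lt(abs(mean(ch$samples_beta) - 0.025), 3 * sd(ch$samples_beta))
  # and the group contrast is still centred near the simulated delta
  expect_lt(abs(mean(ch$samples_D) - 6), 3 * sd(ch$samples_D))
})

test_that("fit rejects degenerate designs", {
  tab <- make_trait_table(5, seed = 1)
  one_group <- tab[tab$group == "NC", ]
  expect_error(fit_two_group_model(one_group, "x", "F1"),
               class = "cryofx_design_error")
  expect_error(fit_two_group_model(tab, "nope", "F1"),
               class = "cryofx_design_error")
  tiny <- tab[c(1, 2, 6), ]  # 2 NC, 1 VT
  expect_error(fit_two_group_model(tiny, "x", "F1"),
               class = "cryofx_design_error")
  expect_error(fit_two_group_model(tab, "x", "F1", use_covariate = TRUE),
               class = "cryofx_config_error")  # covariate column absent
})

test_that("summarize_posterior: P0 conventions and Normal(2,1) closed form", {
  sym <- summarize_posterior(rep(c(-1, 1), 200))
  expect_equal(sym$P0, 0.5)
  expect_equal(summarize_posterior(abs(rnorm(500)) + 0.1)$P0, 1.0)
  # zero draws excluded from the numerator; zero mean reported positive side
  expect_equal(summarize_posterior(c(-1, 0, 0, 1, rep(c(-2, 2), 100)))$P0, 0.5)

  set.seed(31)
  s <- summarize_posterior(rnorm(5000, 2, 1))
  expect_lt(abs(s$hpd_low - (2 - 1.96)), 0.1)
  expect_lt(abs(s$hpd_high - (2 + 1.96)), 0.1)
  expect_lt(abs(s$P0 - pnorm(2)), 0.01)
})

test_that("hpd_interval: tie-break, mass concentration, closed form, errors", {
  expect_equal(hpd_interval(1:100, 0.95), c(low = 1, high = 95))
  expect_equal(hpd_interval(c(0, 0, 0, 0, 10), 0.8), c(low = 0, high = 0))
  # single-sample HPD endpoints jitter more than plain quantiles (the
  # narrowest-window index is noisy), so calibrate on the mean of 20 draws
  set.seed(12)
  h <- rowMeans(replicate(20, hpd_interval(rnorm(10000), 0.95)))
  expect_lt(abs(h[["low"]] + 1.96), 0.05)
  expect_lt(abs(h[["high"]] - 1.96), 0.05)
  expect_error(hpd_interval(1:5, 0.95), "too few")
  expect_error(hpd_interval(1:100, 1.2), "prob")
})

test_that("geweke_z: undefined flag, null calibration, forced drift", {
  z0 <- geweke_z(rep(3, 1000))
  expect_true(is.na(z0))
  expect_true(attr(z0, "undefined"))

  set.seed(99)
  z <- replicate(200, geweke_z(rnorm(5000)))
  expect_true(all(is.finite(z)))
  frac <- mean(abs(z) > 1.96)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)

  set.seed(4)
  expect_gt(abs(geweke_z(c(rnorm(2500), rnorm(2500, 5)))), 10)
  expect_error(geweke_z(rnorm(50)), "window")
})

test_that("mc_se_batch_means: iid closed form, homogeneity, AR(1) inflation", {
  set.seed(8)
  x <- rnorm(5000)
  m <- mc_se_batch_means(x)
  expect_gt(m, (1 / sqrt(5000)) / 1.5)
  expect_lt(m, (1 / sqrt(5000)) * 1.5)
  expect_equal(mc_se_batch_means(7 * x), 7 * m)

  set.seed(3)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  ratio <- mc_se_batch_means(ar) / (sd(ar) / sqrt(5000))
  target <- sqrt((1 + 0.9) / (1 - 0.9))  # ~4.36
  expect_gt(ratio, target / 2)
  expect_lt(ratio, target * 2)
  expect_error(mc_se_batch_means(rnorm(100)), "too few")
})

test_that("relevant_value is one third of the sample SD", {
  x <- c(1, 4, 7)  # sd = 3
  expect_equal(relevant_value(x), 1.0)
  expect_equal(relevant_value(c(0, 2)), sqrt(2) / 3)
  expect_warning(r0 <- relevant_value(c(5, 5, 5)), "identical")
  expect_equal(r0, 0)
  # sampling distribution: configured sd 450, n = 60 pooled
  set.seed(17)
  r <- relevant_value(rnorm(60, 0, 450))
  expect_lt(abs(r - 150), 3 * 450 / (3 * sqrt(2 * 59)))
})

test_that("decide_relevance applies both strict inequalities", {
  mk <- function(D, P0) structure(
    list(D_mean = D, P0 = P0, hpd_low = D - 1, hpd_high = D + 1,
         mcse = 0.01, geweke_z = 0, n_saved = 100),
    class = "posterior_summary")
  d1 <- decide_relevance(mk(-437.4, 0.99), 150)
  expect_true(d1$relevant)
  expect_equal(d1$criterion_trace$abs_D, 437.4)
  expect_false(decide_relevance(mk(100, 0.99), 150)$relevant)
  expect_false(decide_relevance(mk(500, 0.80), 150)$relevant)  # P0 not > 0.8
  expect_false(decide_relevance(mk(150, 0.99), 150)$relevant)  # |D| not > R
})

test_that("compare_traits assembles one decision row per comparison", {
  # n large enough that the null rule rate P(|Z| > (sd/3)/(sd*sqrt(2/n)))
  # is negligible (~1e-3 at n = 200), so the F2 null row is a stable FALSE
  cfg <- pheno_sim_config(n_per_group_per_generation = 200,
                          trait_means = c(w = 100), trait_sds = c(w = 10),
                          group_deltas = list(w = c(F1 = 30)),
                          generations = c("F1", "F2"), seed = 4)
  tab <- gen_phenotype_table(cfg)
  rep <- compare_traits(tab, config = gibbs_config(n_iter = 8000,
                                                   burn_in = 1000, seed = 5))
  expect_equal(nrow(rep), 2)
  expect_true(rep$relevant[rep$generation == "F1"])   # 3-sd shift
  expect_false(rep$relevant[rep$generation == "F2"])  # null
})
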