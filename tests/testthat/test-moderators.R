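test_that("subgroup pooling with one level equals overall pooling", {
  set.seed(5)
  eff <- dplyr::mutate(null_effects(6), ethnicity = "Caucasians")
  sg <- subgroup_pool(eff, by = "ethnicity")
  overall <- sg[sg$level == "overall", ]
  single <- sg[sg$level == "Caucasians", ]
  expect_equal(single$or, overall$or, tolerance = 1e-12)
  expect_equal(single$se, overall$se, tolerance = 1e-12)
})

test_that("fixed-effect subgroup estimates re-pool to the overall estimate", {
  set.seed(8)
  for (i in 1:10) {
    eff <- dplyr::mutate(null_effects(9),
                         ethnicity = rep(c("Asians", "Caucasians", "Asians"), 3))
    sg <- subgroup_pool(eff, by = "ethnicity", method = "fixed")
    overall <- sg[sg$level == "overall", ]
    levels <- sg[sg$level != "overall", ]
    w <- 1 / levels$se^2
    repooled <- sum(w * levels$log_or) / sum(w)
    expect_equal(repooled, overall$log_or, tolerance = 1e-10)
    expect_equal(sqrt(1 / sum(w)), overall$se, tolerance = 1e-10)
  }
})

test_that("subgroup pooling recovers group-specific true odds ratios", {
  # two strata with true ORs 2.0 and 1.0, no between-study variance,
  # large samples: each stratum CI should cover its truth in >= 90% of
  # seeded replicates
  hits_a <- 0; hits_b <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    a <- simulate_studies(sim_config(k = 5, theta = log(2), tau2 = 0,
                                     maf_range = c(0.25, 0.35),
                                     n_case_range = c(800, 1200),
                                     n_ctrl_range = c(800, 1200),
                                     ethnicity = "Asians", seed = 20000 + r))
    b <- simulate_studies(sim_config(k = 5, theta = 0, tau2 = 0,
                                     maf_range = c(0.25, 0.35),
                                     n_case_range = c(800, 1200),
                                     n_ctrl_range = c(800, 1200),
                                     ethnicity = "Caucasians", seed = 40000 + r))
    b$study_id <- paste0("B", b$study_id)
    b$control_group_id <- b$study_id
    eff <- study_effects(dplyr::bind_rows(a, b), "allele")
    sg <- subgroup_pool(eff, by = "ethnicity", method = "fixed")
    asian <- sg[sg$level == "Asians", ]
    cauc <- sg[sg$level == "Caucasians", ]
    hits_a <- hits_a + (asian$ci_low <= 2 && 2 <= asian$ci_high)
    hits_b <- hits_b + (cauc$ci_low <= 1 && 1 <= cauc$ci_high)
  }
  expect_gte(hits_a / n_rep, 0.9)
  expect_gte(hits_b / n_rep, 0.9)
})

test_that("leave-one-out reduces to the other study at k = 2", {
  eff <- eff_tbl(c(0.2, 0.8), c(0.1, 0.3), study_id = c("A", "B"))
  loo <- leave_one_out(eff)
  expect_equal(nrow(loo), 2)
  expect_equal(loo$log_or[loo$omitted_study_id == "A"], 0.8)
  expect_equal(loo$log_or[loo$omitted_study_id == "B"], 0.2)
  expect_error(leave_one_out(eff[1, ]), class = "snpmeta_sensitivity_error")
})

test_that("leave-one-out is stable for homogeneous effects and ranks outliers", {
  set.seed(14)
  se <- runif(12, 0.08, 0.12)
  eff <- eff_tbl(rnorm(12, 0.4, 0.01), se, study_id = sprintf("S%02d", 1:12))
  full <- meta_pool(eff)
  loo <- leave_one_out(eff)
  expect_true(all(abs(loo$or - full$or) / full$or < 0.01))
  expect_true(all(loo$conclusion_stable))

  outlier <- eff
  outlier$log_or[5] <- 3
  loo2 <- leave_one_out(outlier, method = "fixed")
  full2 <- pool_fixed(outlier)
  shifts <- abs(loo2$log_or - full2$log_or)
  expect_equal(which.max(shifts), 5)
})

test_that("meta-regression recovers a binary moderator slope", {
  set.seed(99)
  x <- rep(c(0, 1), each = 20)
  eff <- eff_tbl(rnorm(40, 0.1 + 0.5 * x, 0.05), rep(0.05, 40))
  fit <- meta_regress(eff, data.frame(x = x), mode = "multivariate")
  slope <- tidy(fit)
  slope <- slope$coefficient[slope$term == "x"]
  expect_gte(slope, 0.4)
  expect_lte(slope, 0.6)
})

test_that("univariate mode with one moderator equals multivariate", {
  set.seed(17)
  eff <- null_effects(12)
  x <- rnorm(12)
  uni <- tidy(meta_regress(eff, data.frame(x = x), mode = "univariate"))
  multi <- tidy(meta_regress(eff, data.frame(x = x), mode = "multivariate"))
  expect_equal(uni, multi[multi$term == "x", ], tolerance = 1e-12)
})

test_that("degenerate designs are rejected or pruned", {
  set.seed(3)
  eff <- null_effects(10)
  expect_warning(
    fit <- meta_regress(eff, data.frame(x = rnorm(10), z = rep(0, 10))),
    "constant")
  expect_false("z" %in% tidy(fit)$term)
  expect_error(suppressWarnings(meta_regress(eff, data.frame(z = rep(2, 10)))),
               class = "snpmeta_metareg_error")
  x <- rnorm(10)
  expect_error(meta_regress(eff, data.frame(x = x, y = 2 * x)),
               class = "snpmeta_singular_design")
  expect_error(meta_regress(eff[1:3, ], data.frame(x = x[1:3], y = rnorm(3))),
               class = "snpmeta_metareg_error")
})

test_that("intercept-only meta-regression reproduces random-effects pooling", {
  set.seed(23)
  eff <- null_effects(8)
  # the moment estimator of residual tau2 reduces to DerSimonian-Laird
  # for the intercept-only design, so the two routes must agree exactly
  X <- matrix(1, nrow = 8, ncol = 1)
  fit <- snpmeta:::fit_wls(X, eff$log_or, eff$se^2)
  pooled <- pool_random(eff)
  het <- heterogeneity(eff)
  expect_equal(fit$tau2, het$tau2, tolerance = 1e-12)
  expect_equal(fit$beta[1], pooled$log_or, tolerance = 1e-12)
  expect_equal(fit$se[1], pooled$se, tolerance = 1e-12)
})

test_that("meta-regression matches metafor's moment-estimator fit", {
  skip_if_not_installed("metafor")
  set.seed(31)
  eff <- null_effects(15)
  x <- rnorm(15); z <- rbinom(15, 1, 0.5)
  fit <- tidy(meta_regress(eff, data.frame(x = x, z = z), mode = "multivariate"))
  ref <- metafor::rma(yi = eff$log_or, sei = eff$se, mods = ~ x + z,
                      method = "DL", test = "t")
  s <- coef(summary(ref))
  expect_equal(fit$coefficient, s$estimate, tolerance = 1e-8)
  expect_equal(fit$se, s$se, tolerance = 1e-8)
  expect_equal(fit$p, s$pval, tolerance = 1e-8)
  expect_equal(fit$ci_low, s$ci.lb, tolerance = 1e-8)
})

test_that("standard cohort moderators are encoded as documented", {
  sim <- simulate_tlr4_cohort(seed = 2)
  eff <- study_effects(sim, "allele")
  M <- snpmeta:::moderator_matrix(eff, c("sample_size", "ethnicity",
                                         "disease", "snp"))
  expect_equal(M$sample_size, eff$n_case + eff$n_ctrl)
  expect_equal(M$ethnicity, as.numeric(eff$ethnicity == "Caucasians"))
  expect_equal(M$disease, as.numeric(eff$disease == "CD"))
  expect_equal(M$snp, as.numeric(eff$snp == "rs4986791"))
})

test_that("permutation p-values are seeded, bounded and detect separation", {
  set.seed(41)
  eff <- null_effects(15)
  x <- rnorm(15)
  p1 <- permute_pvalues(eff, data.frame(x = x), n_perm = 199, seed = 10)
  p2 <- permute_pvalues(eff, data.frame(x = x), n_perm = 199, seed = 10)
  expect_equal(p1, p2)
  expect_gte(p1$p, 1 / 200)
  expect_lte(p1$p, 1)

  # moderator perfectly ordered with strongly sloped effects: no
  # permutation can beat the observed ordering
  k <- 15
  xo <- seq_len(k)
  eff_o <- eff_tbl(0.3 * xo + rnorm(k, 0, 0.001), rep(0.05, k))
  p <- permute_pvalues(eff_o, data.frame(x = xo), n_perm = 199, seed = 4)
  expect_equal(p$p, 1 / 200)

  expect_error(permute_pvalues(eff, data.frame(x = x), n_perm = 50, seed = 1),
               class = "snpmeta_metareg_error")
  expect_error(permute_pvalues(eff, data.frame(x = x), n_perm = 199),
               class = "snpmeta_metareg_error")
})

test_that("bonferroni adjustment scales moderator p-values only", {
  set.seed(55)
  eff <- null_effects(12)
  M <- data.frame(x = rnorm(12), z = rnorm(12))
  plain <- tidy(meta_regress(eff, M))
  adj <- tidy(meta_regress(eff, M, adjust = "bonferroni"))
  idx <- plain$term != "intercept"
  expect_equal(adj$p[idx], pmin(1, plain$p[idx] * 2))
  expect_equal(adj$p[!idx], plain$p[!idx])
})
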