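test_that("single-table odds ratios match hand arithmetic", {
  sym <- table_effect(10, 10, 10, 10)
  expect_equal(sym$or, 1)
  expect_equal(sym$log_or, 0)
  expect_equal(sym$se, sqrt(0.4))
  expect_false(sym$corrected)

  plain <- table_effect(20, 80, 10, 90)
  expect_equal(plain$or, 2.25)
  expect_equal(plain$se, sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90))

  haldane <- table_effect(0, 10, 5, 5)
  expect_true(haldane$corrected)
  expect_equal(haldane$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(haldane$or, 0.047619, tolerance = 1e-4)

  expect_error(table_effect(0, 0, 5, 5), class = "snpmeta_inestimable_effect")
  expect_error(table_effect(1, 2, 0, 5, correction = "none"),
               class = "snpmeta_inestimable_effect")
  all_corr <- table_effect(20, 80, 10, 90, correction = "all")
  expect_true(all_corr$corrected)
  expect_equal(all_corr$or, (20.5 * 90.5) / (80.5 * 10.5))
})

test_that("two-study pooling reproduces the hand-calculated oracle", {
  eff <- eff_tbl(c(0.6931, 0), c(0.2, 0.2))

  fixed <- pool_fixed(eff)
  expect_equal(fixed$log_or, 0.34655, tolerance = 1e-10)
  expect_equal(fixed$or, exp(0.34655), tolerance = 1e-10)
  expect_equal(fixed$or, 1.4142, tolerance = 1e-4)
  expect_equal(fixed$se, sqrt(1 / 50), tolerance = 1e-12)

  het <- heterogeneity(eff)
  expect_equal(het$q, 50 * 0.34655^2, tolerance = 1e-10)   # = 6.00485
  expect_equal(het$q, 6.005, tolerance = 1e-3)
  expect_equal(het$df, 1)
  expect_equal(het$i2, 100 * (het$q - 1) / het$q, tolerance = 1e-10)
  expect_equal(het$i2, 83.35, tolerance = 1e-3)
  expect_equal(het$tau2, (het$q - 1) / (50 - 25), tolerance = 1e-10)
  expect_equal(het$tau2, 0.2002, tolerance = 1e-3)

  random <- pool_random(eff)
  expect_equal(random$log_or, 0.34655, tolerance = 1e-10)  # equal weights preserved
  expect_gt(random$se, fixed$se)
  expect_gt(random$ci_high - random$ci_low, fixed$ci_high - fixed$ci_low)
  w_star <- 1 / (0.04 + het$tau2)
  expect_equal(random$se, sqrt(1 / (2 * w_star)), tolerance = 1e-10)
})

test_that("degenerate pooling cases behave as identities", {
  one <- eff_tbl(0.5, 0.25)
  for (pool in list(pool_fixed, pool_random)) {
    res <- pool(one)
    expect_equal(res$log_or, 0.5)
    expect_equal(res$se, 0.25)
    expect_equal(res$ci_low, exp(0.5 - 1.959964 * 0.25))
  }
  expect_error(heterogeneity(one), class = "snpmeta_heterogeneity_error")
  expect_error(pool_fixed(eff_tbl(numeric(0), numeric(0))),
               class = "snpmeta_no_effects")

  same <- eff_tbl(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(pool_fixed(same)$log_or, 0.3)
  het <- heterogeneity(same)
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)
  expect_equal(het$tau2, 0)
  # tau2 = 0 makes random pooling coincide with fixed
  expect_equal(glance(pool_random(same))[c("or", "ci_low", "ci_high", "se")],
               glance(pool_fixed(same))[c("or", "ci_low", "ci_high", "se")])
})

test_that("model selection follows the conventional rule by default", {
  low_het <- tibble::tibble(p_q = 0.129, i2 = 26.058)
  high_het <- tibble::tibble(p_q = 0.005, i2 = 83)
  expect_equal(select_model(low_het, "conventional"), "fixed")
  expect_equal(select_model(high_het, "conventional"), "random")
  # the literal published wording reverses the choice
  expect_equal(select_model(high_het, "paper"), "fixed")
  expect_equal(select_model(low_het, "paper"), "random")
  # I2 alone can trigger the switch
  expect_equal(select_model(tibble::tibble(p_q = 0.2, i2 = 60), "conventional"),
               "random")
})

test_that("pooling matches metafor on random effect sets", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (k in c(2, 3, 4, 8)) {
    eff <- null_effects(k)
    fe <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "FE")
    dl <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    f <- pool_fixed(eff)
    r <- pool_random(eff)
    h <- heterogeneity(eff)
    expect_equal(f$log_or, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(f$se, fe$se, tolerance = 1e-10)
    expect_equal(f$p, fe$pval, tolerance = 1e-10)
    expect_equal(r$log_or, as.numeric(dl$beta), tolerance = 1e-10)
    expect_equal(r$se, dl$se, tolerance = 1e-10)
    expect_equal(h$q, dl$QE, tolerance = 1e-10)
    expect_equal(h$tau2, dl$tau2, tolerance = 1e-10)
    expect_equal(h$i2, dl$I2, tolerance = 1e-8)
  }
})

test_that("pooling invariants hold across generated effect sets", {
  set.seed(7)
  for (i in 1:25) {
    eff <- null_effects(sample(2:10, 1))
    f <- pool_fixed(eff)
    r <- pool_random(eff)
    expect_gte(f$log_or, min(eff$log_or) - 1e-12)
    expect_lte(f$log_or, max(eff$log_or) + 1e-12)
    expect_gte(r$se, f$se - 1e-14)
    expect_equal(sum(f$weights), 1, tolerance = 1e-12)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    shuffled <- eff[sample.int(nrow(eff)), ]
    expect_equal(pool_fixed(shuffled)$log_or, f$log_or, tolerance = 1e-12)
    expect_equal(pool_random(shuffled)$log_or, r$log_or, tolerance = 1e-12)
  }
})

test_that("rescaling standard errors moves I2 but leaves its definition intact", {
  eff <- eff_tbl(c(0.6931, 0), c(0.2, 0.2))
  wide <- eff_tbl(eff$log_or, eff$se * 10)
  h1 <- heterogeneity(eff)
  h10 <- heterogeneity(wide)
  expect_equal(h10$q, h1$q / 100, tolerance = 1e-12)
  expect_lt(h10$i2, h1$i2)
  expect_equal(h10$i2, 0)  # Q drops below df
})

test_that("meta_pool auto mode dispatches on the heterogeneity rule", {
  homog <- eff_tbl(rep(0.3, 5), rep(0.2, 5))
  expect_equal(meta_pool(homog)$model_effects, "fixed")
  heterog <- eff_tbl(c(-1, 1, -1, 1, -1), rep(0.1, 5))
  expect_equal(meta_pool(heterog)$model_effects, "random")
  expect_equal(meta_pool(heterog, rule = "paper")$model_effects, "fixed")
  expect_equal(meta_pool(heterog, method = "fixed")$model_effects, "fixed")
  # k = 1 has no heterogeneity to judge: fixed identity
  expect_equal(meta_pool(eff_tbl(0.2, 0.1))$model_effects, "fixed")
})

test_that("tidy and glance expose the pooled result as tables", {
  sim <- simulate_studies(sim_config(k = 5, theta = 0.3, seed = 12))
  eff <- study_effects(sim, "allele")
  pooled <- meta_pool(eff)
  td <- tidy(pooled)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(pooled)
  expect_equal(gl$k, 5)
  expect_true(all(c("or", "ci_low", "ci_high", "p", "q", "i2", "tau2") %in%
                    names(gl)))
})
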