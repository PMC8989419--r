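test_that("simulated genotypes follow Hardy-Weinberg proportions at the requested MAF", {
  spec <- simulation_spec(n_subjects = 10000, seed = 4,
                          maf = c(rs1059047 = 0.5, rs1136450 = 0.2))
  g <- simulate_genotypes(spec)
  expect_lt(abs(mean(g$dosage[, "rs1059047"]) - 1.0), 0.02)
  expect_lt(abs(mean(g$dosage[, "rs1136450"] == 1L) - 2 * 0.2 * 0.8), 0.01)
})

test_that("simulated genotype counts pass the exact HWE test at the nominal rate", {
  pass <- vapply(1:200, function(r) {
    spec <- simulation_spec(n_subjects = 300, seed = 5000 + r)
    g <- simulate_genotypes(spec)
    v <- g$dosage[, "rs1124"]
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2)) > 0.05
  }, logical(1))
  # exact test is conservative, so the pass rate is at least ~95%
  expect_gte(mean(pass), 0.90)
})

test_that("pairwise LD blocks reach the requested r-squared", {
  spec <- simulation_spec(
    n_subjects = 20000, seed = 12,
    maf = c(rs1059047 = 0.3, rs1136450 = 0.3),
    ld_blocks = list(list(snps = c("rs1059047", "rs1136450"), r2 = 0.6)))
  g <- simulate_genotypes(spec)
  r2 <- cor(g$dosage[, "rs1059047"], g$dosage[, "rs1136450"])^2
  expect_lt(abs(r2 - 0.6), 0.05)
})

test_that("intercept calibration hits the target prevalence", {
  spec <- simulation_spec(seed = 6, target_prevalence = 0.43)
  expect_equal(calibrate_intercept(spec), qlogis(0.43))  # closed form, no effects

  spec2 <- simulation_spec(
    n_subjects = 50000, seed = 6, target_prevalence = 0.43,
    maf = c(rs721917 = 0.45),
    effects = list(list(snps = "rs721917", labels = "d", log_or = log(3))))
  b0 <- calibrate_intercept(spec2)
  sim <- simulate_cohort(spec2)
  expect_lt(abs(mean(sim$cohort$status) - 0.43), 0.012)

  spec3 <- simulation_spec(seed = 6, target_prevalence = 1 - 1e-12,
                           effects = list(list(snps = "rs721917", labels = "d",
                                               log_or = -30)))
  expect_error(calibrate_intercept(spec3, n_ref = 2000), "bracket")
})

test_that("planted epistatic effect is recovered in the selected-vs-complement OR", {
  spec <- simulation_spec(
    n_subjects = 2000, seed = 19,
    effects = list(list(snps = c("rs1130866", "rs1124"),
                        labels = c("a", "d"), log_or = log(3))))
  sim <- simulate_cohort(spec)
  pt <- partition_genotypes(effect_type(c("a", "d")))
  a <- assign_subjects(pt, sim$genotypes, c("rs1130866", "rs1124"))
  tab <- build_2x2(sim$cohort$status, a)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or, 2.3)
  expect_lt(or, 3.9)
  # the truth record reproduces each subject's case probability exactly
  expect_equal(sim$truth$prob,
               plogis(sim$truth$beta0 + sim$truth$eta), tolerance = 1e-12)
})

test_that("covariate-only effects leave SNP tests null", {
  spec <- simulation_spec(
    n_subjects = 1500, seed = 23,
    covariate_betas = c(culture_positive = log(2)))
  sim <- simulate_cohort(spec)
  m1 <- run_model(1, sim$genotypes, sim$cohort)
  fam <- attr(m1, "all_tests")
  expect_false(any(fam$significant_fdr, na.rm = TRUE))
  # but the planted covariate association is visible
  tab <- table(sim$cohort$status, sim$cohort$culture_positive)
  expect_lt(group_compare_p(tab)$p_value, 0.01)
})

test_that("missingness injection is reproducible and hits the requested rate", {
  spec <- simulation_spec(n_subjects = 1000, seed = 2)
  g <- simulate_genotypes(spec)
  expect_identical(inject_missing(g, 0, seed = 1)$dosage, g$dosage)
  gm <- inject_missing(g, 0.1, seed = 3)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.1), 0.01)
  gm2 <- inject_missing(g, 0.1, seed = 3)
  expect_identical(gm$dosage, gm2$dosage)
})

test_that("the same seed reproduces the cohort bit-identically", {
  spec <- simulation_spec(n_subjects = 150, seed = 11, missing_rate = 0.02,
                          effects = list(list(snps = "rs1124", labels = "a",
                                              log_or = log(2))))
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(simulation_spec(n_subjects = 150, seed = 12))
  expect_false(identical(s1$cohort$status, s3$cohort$status))
})

test_that("cohort demographics match the configured study profile", {
  spec <- simulation_spec(n_subjects = 20000, seed = 14)
  sim <- simulate_cohort(spec)
  co <- sim$cohort
  expect_lt(abs(mean(co$age_months) - 3.5), 0.35)
  expect_true(all(co$age_months <= 24 & co$age_months >= 0))
  expect_lt(abs(mean(co$female) - 0.35), 0.02)
  expect_lt(abs(mean(co$non_white) - 0.30), 0.02)
  expect_gt(cor(co$age_months, co$weight_kg), 0.5)
  expect_lt(abs(mean(co$status) - 0.425), 0.02)
})

test_that("power study separates planted effects from the null", {
  null_spec <- simulation_spec(n_subjects = 150, seed = 41)
  planted <- simulation_spec(
    n_subjects = 2000, seed = 43,
    effects = list(list(snps = c("rs1130866", "rs1124"),
                        labels = c("a", "d"), log_or = log(3))))
  res <- power_study(list(null = null_spec, planted = planted),
                     reps = 5, k = 2)
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$power[res$scenario == "null"]))
  expect_equal(res$power[res$scenario == "planted"], 1)
  expect_lte(res$any_discovery_rate[res$scenario == "null"], 0.4)
})
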