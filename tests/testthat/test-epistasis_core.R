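test_that("effect-type enumeration yields 2/8/26 types in deterministic order", {
  expect_equal(vapply(enumerate_effect_types(1), format, character(1)),
               c("a1", "d1"))
  expect_equal(vapply(enumerate_effect_types(2), format, character(1)),
               c("a1", "d1", "a2", "d2", "a1a2", "a1d2", "d1a2", "d1d2"))
  expect_length(enumerate_effect_types(3), 26)
  expect_equal(format(effect_type(c("a", "silent", "d"))), "a1d3")
  expect_error(effect_type(c("silent", "silent")), "all silent")
  expect_error(enumerate_effect_types(4), "k must be")
})

test_that("a1d2 partition reproduces the worked two-locus example", {
  pt <- partition_genotypes(effect_type(c("a", "d")))
  expect_setequal(pt$selected_labels, c("AABb", "aaBb"))
  expect_setequal(pt$complement_labels,
                  c("AABB", "AAbb", "AaBB", "AaBb", "Aabb", "aaBB", "aabb"))
  # single-SNP dominant: het vs pooled homozygotes
  pd <- partition_genotypes(effect_type("d"))
  expect_equal(pd$selected_labels, "Aa")
  expect_setequal(pd$complement_labels, c("AA", "aa"))
  # silent locus is unconstrained: |selected| = 2 x 3 x 1
  p3 <- partition_genotypes(effect_type(c("a", "silent", "d")))
  expect_equal(nrow(p3$selected), 6)
  expect_equal(nrow(p3$selected) + nrow(p3$complement), 27)
})

test_that("partitions are total and disjoint for every effect type and convention", {
  for (conv in c("paper_literal", "orthogonal")) {
    for (k in 1:3) {
      for (et in enumerate_effect_types(k)) {
        pt <- partition_genotypes(et, conv)
        n_all <- nrow(pt$selected) + nrow(pt$complement) + nrow(pt$excluded)
        expect_equal(n_all, 3^k)
        keys <- c(apply(pt$selected, 1, paste, collapse = ""),
                  apply(pt$complement, 1, paste, collapse = ""),
                  apply(pt$excluded, 1, paste, collapse = ""))
        expect_equal(anyDuplicated(keys), 0)
        expect_gt(nrow(pt$selected), 0)
        expect_gt(nrow(pt$complement), 0)
        if (conv == "paper_literal") expect_equal(nrow(pt$excluded), 0)
      }
    }
  }
})

test_that("subjects map to selected/complement/excluded as the worked example states", {
  panel <- toy_panel(2)
  pt <- partition_genotypes(effect_type(c("a", "d")))
  g <- toy_genotypes(rbind(c(0L, 1L),   # AABb -> selected
                           c(1L, 1L),   # AaBb -> complement
                           c(NA, 1L),   # missing -> excluded
                           c(2L, 1L)),  # aaBb -> selected
                     panel)
  a <- assign_subjects(pt, g, panel$rsid)
  expect_equal(as.character(a), c("selected", "complement", "excluded", "selected"))

  # orthogonal convention: heterozygote at an additive locus is excluded
  pto <- partition_genotypes(effect_type(c("a", "d")), "orthogonal")
  ao <- assign_subjects(pto, g, panel$rsid)
  expect_equal(as.character(ao), c("complement", "excluded", "excluded", "selected"))
})

test_that("2x2 construction matches a hand tally and rejects empty input", {
  assign <- factor(c(rep("selected", 3), rep("complement", 7)),
                   levels = c("selected", "complement", "excluded"))
  status <- c(1, 1, 0, 1, 1, 1, 0, 0, 0, 0)
  tab <- build_2x2(status, assign)
  expect_equal(unname(tab), matrix(c(2, 3, 1, 4), 2, byrow = TRUE))
  expect_error(build_2x2(status, factor(rep("excluded", 10),
                                        levels = levels(assign))),
               "all subjects excluded")

  # brute-force tally on random fixtures
  set.seed(21)
  for (i in 1:20) {
    a <- factor(sample(levels(assign), 30, TRUE), levels = levels(assign))
    y <- sample(0:1, 30, TRUE)
    if (!any(a != "excluded") || length(unique(y[a != "excluded"])) < 2) next
    tab <- build_2x2(y, a)
    expect_equal(tab["case", "selected"], sum(y == 1 & a == "selected"))
    expect_equal(tab["control", "complement"], sum(y == 0 & a == "complement"))
  }
})

test_that("covariate strata split sex x race x median age with documented tie-break", {
  co <- toy_cohort(rep(c(1, 0), 4),
                   age = c(1, 1, 1, 1, 10, 10, 10, 10),
                   female = c(0, 0, 1, 1, 0, 0, 1, 1),
                   non_white = c(0, 1, 0, 1, 0, 1, 0, 1))
  s <- stratify_covariates(co)
  expect_equal(nlevels(droplevels(s)), 8)
  # all-male all-White young cohort collapses to one stratum
  co1 <- toy_cohort(c(1, 0, 1), age = c(2, 2, 2), female = c(0, 0, 0),
                    non_white = c(0, 0, 0))
  expect_equal(nlevels(droplevels(stratify_covariates(co1))), 1)
  # ages at the median go to the young stratum
  co2 <- toy_cohort(c(1, 0, 1), age = c(1, 5, 9), female = c(0, 0, 0),
                    non_white = c(0, 0, 0))
  s2 <- stratify_covariates(co2)
  expect_equal(grepl("young", as.character(s2)), c(TRUE, TRUE, FALSE))
  # missing stratification covariates get their own stratum
  co2$female[2] <- NA
  expect_equal(as.character(stratify_covariates(co2))[2], "missing")
})

test_that("Mantel-Haenszel estimate matches closed forms and the reference implementation", {
  t1 <- matrix(c(10, 20, 5, 40), 2, byrow = TRUE)
  r <- cmh_estimate(t1)
  expect_equal(r$or_mh, 4)                       # ad/bc exactly
  expect_equal(cmh_estimate(list(t1, t1))$or_mh, 4)  # pooling invariance

  # heterogeneous strata against a direct transcription of the formulas
  t2 <- matrix(c(12, 9, 8, 30), 2, byrow = TRUE)
  r2 <- cmh_estimate(list(t1, t2))
  a <- c(10, 12); b <- c(20, 9); cc <- c(5, 8); d <- c(40, 30)
  n <- a + b + cc + d
  or_oracle <- sum(a * d / n) / sum(b * cc / n)
  expect_equal(r2$or_mh, or_oracle, tolerance = 1e-12)
  P <- (a + d) / n; Q <- (b + cc) / n; R <- a * d / n; S <- b * cc / n
  v <- sum(P * R) / (2 * sum(R)^2) + sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  expect_equal(r2$ci95,
               exp(log(or_oracle) + c(-1, 1) * qnorm(0.975) * sqrt(v)),
               tolerance = 1e-12)

  # cross-check OR and p against stats::mantelhaen.test
  arr <- array(c(t(t1), t(t2)), dim = c(2, 2, 2))
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(r2$or_mh, unname(mh$estimate), tolerance = 1e-9)
  expect_equal(r2$p_cmh, mh$p.value, tolerance = 1e-9)

  # degenerate strata are dropped, all-degenerate errors
  expect_message(r3 <- cmh_estimate(list(t1, matrix(c(0, 0, 3, 4), 2, byrow = TRUE))),
                 "dropping")
  expect_equal(r3$or_mh, 4)
  expect_error(suppressMessages(cmh_estimate(matrix(c(0, 0, 1, 2), 2, byrow = TRUE))),
               "degenerate")
})

test_that("single-SNP additive and dominant tests are complementary under the literal rule", {
  set.seed(5)
  spec <- simulation_spec(n_subjects = 200, seed = 31)
  sim <- simulate_cohort(spec)
  m1 <- run_model(1, sim$genotypes, sim$cohort)
  fam <- attr(m1, "all_tests")
  for (rs in unique(fam$snp1)) {
    or_a <- fam$or_mh[fam$snp1 == rs & fam$effect_type == "a1"]
    or_d <- fam$or_mh[fam$snp1 == rs & fam$effect_type == "d1"]
    expect_equal(or_a, 1 / or_d, tolerance = 1e-12)
  }
})

test_that("adjusted logistic p reduces to the univariate test with constant covariates", {
  set.seed(8)
  n <- 300
  y <- rbinom(n, 1, 0.45)
  x <- rbinom(n, 1, 0.4)
  cov0 <- data.frame(age_months = rep(3, n), female = rep(FALSE, n),
                     non_white = rep(FALSE, n), weight_kg = rep(5, n))
  r <- adjusted_logistic_p(y, x, cov0)
  u <- univariate_logistic(y, x)
  expect_equal(r$p, u$p, tolerance = 1e-6)
  expect_equal(r$or, u$or, tolerance = 1e-6)

  # collinear indicator is flagged with a missing p
  cov1 <- data.frame(age_months = rnorm(n, 3), female = x == 1,
                     non_white = rep(FALSE, n), weight_kg = rnorm(n, 5))
  r2 <- suppressMessages(adjusted_logistic_p(y, x, cov1))
  expect_true(is.na(r2$p))
  expect_true(r2$flag != "")

  r3 <- suppressMessages(
    adjusted_logistic_p(y, rep(1, n), cov0))
  expect_equal(r3$flag, "constant_indicator")
})

test_that("adjusted logistic p detects a strong indicator and stays calibrated under the null", {
  set.seed(99)
  n <- 500
  x <- rbinom(n, 1, 0.3)
  covs <- data.frame(age_months = rlnorm(n, 1, 0.5), female = rbinom(n, 1, 0.4) == 1,
                     non_white = rbinom(n, 1, 0.3) == 1, weight_kg = rnorm(n, 6, 1))
  y <- rbinom(n, 1, plogis(-1.2 + log(5) * x))
  expect_lt(adjusted_logistic_p(y, x, covs)$p, 0.001)

  hits <- replicate(200, {
    y0 <- rbinom(1000, 1, 0.43)
    x0 <- rbinom(1000, 1, 0.3)
    cv <- data.frame(age_months = rlnorm(1000, 1, 0.5),
                     female = rbinom(1000, 1, 0.4) == 1,
                     non_white = rbinom(1000, 1, 0.3) == 1,
                     weight_kg = rnorm(1000, 6, 1))
    adjusted_logistic_p(y0, x0, cv)$p > 0.05
  })
  expect_lt(abs(mean(hits) - 0.95), 0.04)
})

test_that("BH q-values and flags match a brute-force step-up on random vectors", {
  brute <- function(p, q = 0.05) {
    m <- length(p); o <- order(p)
    thresh <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(thresh)) rej[o[seq_len(max(thresh))]] <- TRUE
    qv <- rev(cummin(rev(m * p[o] / seq_len(m)))); qv <- pmin(qv, 1)
    list(q = qv[order(o)], rej = rej)
  }
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(c(1, 2, 3), 1)
    r <- bh_fdr(p)
    b <- brute(p)
    expect_equal(r$q_values, b$q, tolerance = 1e-12)
    expect_identical(r$significant, b$rej)
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$significant, rep(TRUE, 4))
  expect_equal(bh_fdr(numeric())$q_values, numeric())
  r <- bh_fdr(c(1, 1, 1))
  expect_equal(r$q_values, c(1, 1, 1))
  expect_false(any(r$significant))
})

test_that("model sweeps enumerate the full test families", {
  spec <- simulation_spec(n_subjects = 60, seed = 3)
  sim <- simulate_cohort(spec)
  m1 <- run_model(1, sim$genotypes, sim$cohort)
  expect_equal(attr(m1, "n_tests"), 28)
  m2 <- run_model(2, sim$genotypes, sim$cohort)
  expect_equal(attr(m2, "n_tests"), 728)
  expect_equal(nrow(attr(m2, "all_tests")), 728)
  # direction annotation is tied to the Mantel-Haenszel OR
  fam <- attr(m2, "all_tests")
  ok <- !is.na(fam$or_mh) & !is.na(fam$direction)
  expect_true(all((fam$or_mh[ok] > 1) == (fam$direction[ok] == "risk")))
  # reported records are sorted by adjusted p and below the threshold
  if (nrow(m2)) {
    expect_true(all(diff(m2$p_adj) >= 0))
    expect_true(all(m2$p_adj < 0.05))
  }
})

test_that("sweep fast path agrees with the explicit partition/assignment route", {
  spec <- simulation_spec(n_subjects = 120, seed = 17, missing_rate = 0.05)
  sim <- simulate_cohort(spec)
  strata <- stratify_covariates(sim$cohort)
  fam <- attr(run_model(2, sim$genotypes, sim$cohort, strata = strata), "all_tests")
  set.seed(2)
  rows <- sample(nrow(fam), 12)
  for (i in rows) {
    et <- effect_type(prmepi:::type_labels_from_string(fam$effect_type[i], 2))
    pt <- partition_genotypes(et)
    a <- assign_subjects(pt, sim$genotypes, c(fam$snp1[i], fam$snp2[i]))
    a <- a[match(sim$cohort$subject_id, sim$genotypes$subject_ids)]
    tabs <- lapply(levels(strata), function(s) {
      idx <- strata == s
      if (!any(idx)) return(NULL)
      matrix(c(sum(sim$cohort$status[idx] == 1 & a[idx] == "selected"),
               sum(sim$cohort$status[idx] == 1 & a[idx] == "complement"),
               sum(sim$cohort$status[idx] == 0 & a[idx] == "selected"),
               sum(sim$cohort$status[idx] == 0 & a[idx] == "complement")),
             2, 2, byrow = TRUE)
    })
    tabs <- Filter(Negate(is.null), tabs)
    r <- tryCatch(suppressMessages(cmh_estimate(tabs)), error = function(e) NULL)
    if (is.null(r)) {
      expect_true(is.na(fam$or_mh[i]) || fam$flag[i] != "")
    } else {
      expect_equal(fam$or_mh[i], r$or_mh, tolerance = 1e-9)
      expect_equal(fam$p_cmh[i], r$p_cmh, tolerance = 1e-9)
    }
  }
})
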