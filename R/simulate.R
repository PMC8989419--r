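#' Paper-informed default minor-allele frequencies
#'
#' Control-group allele percentages where printed (rs721917 0.43, rs1124
#' 0.37, rs4715 0.27, rs17886395 0.16); all other panel SNPs default to
#' 0.25.  These are simulator defaults informed by the study cohort, not
#' population ground truth.
#'
#' @param panel `snp_panel`.
#' @return Named numeric vector of MAFs.
#' @export
default_mafs <- function(panel = load_default_panel()) {
  maf <- stats::setNames(rep(0.25, nrow(panel)), panel$rsid)
  known <- c(rs721917 = 0.43, rs1124 = 0.37, rs4715 = 0.27, rs17886395 = 0.16)
  maf[names(known)[names(known) %in% names(maf)]] <-
    known[names(known) %in% names(maf)]
  maf
}

#' Specify a synthetic case-control cohort
#'
#' The generator emulates the study conditions: roughly 125-160 infants
#' followed after acute respiratory failure, ~43% of whom develop
#' persistent respiratory morbidity; biallelic genotypes in
#' Hardy-Weinberg proportions at panel MAFs; demographics matched to the
#' cohort table (age ~3.5 +/- 4.5 months, 35% female, 30% non-White,
#' weight increasing with age); and disease status drawn from a logistic
#' penetrance model with configurable planted single-SNP / epistatic
#' effects and covariate effects, calibrated to a target prevalence.
#'
#' @param n_subjects cohort size (default 155, the 6-month follow-up).
#' @param maf named rsid -> MAF map (default [default_mafs()]).
#' @param ld_blocks optional list of `list(snps = c(rs1, rs2), r2 = x)`
#'   pairwise LD targets.
#' @param effects list of planted effects, each
#'   `list(snps, labels, log_or, convention)`; `labels` over
#'   `c("a","d","silent")` aligned with `snps`.
#' @param covariate_betas named log-odds per covariate (subset of
#'   age_months, female, non_white, weight_kg, culture_positive, pdad).
#' @param covariate_params overrides for the demographic distributions.
#' @param target_prevalence population-average case probability
#'   (default 0.425).
#' @param missing_rate independent genotype dropout probability.
#' @param timepoint `"6m"` or `"12m"`.
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#' @param panel `snp_panel`.
#' @return A `sim_spec` list.
#' @export
simulation_spec <- function(n_subjects = 155, maf = NULL, ld_blocks = NULL,
                            effects = list(), covariate_betas = numeric(),
                            covariate_params = list(),
                            target_prevalence = 0.425, missing_rate = 0,
                            timepoint = "6m", seed = 1,
                            panel = load_default_panel()) {
  if (is.null(maf)) maf <- default_mafs(panel)
  if (!all(names(maf) %in% panel$rsid)) stopf("maf names must be panel rsids")
  if (any(maf <= 0 | maf > 0.5)) stopf("MAFs must lie in (0, 0.5]")
  full <- default_mafs(panel); full[names(maf)] <- maf; maf <- full
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stopf("target_prevalence must be in (0,1)")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0,1)")
  for (e in effects) {
    if (!all(e$snps %in% panel$rsid)) stopf("planted effect SNP not in panel")
    if (length(e$snps) != length(e$labels)) stopf("effect labels must match its SNPs")
    effect_type(e$labels) # validates
  }
  cp <- list(age_mean = 3.5, age_sd = 4.5, age_max = 24, p_female = 0.35,
             p_non_white = 0.30, p_hispanic = 0.18, weight_intercept = 4,
             weight_slope = 0.5, weight_sd = 0.8, p_culture = 0.52,
             p_pdad = 0.32, p_prm6 = 0.40)
  cp[names(covariate_params)] <- covariate_params
  cb <- c(age_months = 0, female = 0, non_white = 0, weight_kg = 0,
          culture_positive = 0, pdad = 0)
  bad <- setdiff(names(covariate_betas), names(cb))
  if (length(bad)) stopf("unknown covariate beta(s): %s", paste(bad, collapse = ", "))
  cb[names(covariate_betas)] <- covariate_betas
  structure(list(n_subjects = n_subjects, maf = maf, ld_blocks = ld_blocks,
                 effects = effects, covariate_betas = cb, covariate_params = cp,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate, timepoint = timepoint,
                 seed = as.integer(seed), panel = panel),
            class = "sim_spec")
}

# Sample one SNP's dosages from Hardy-Weinberg proportions.
rhwe <- function(n, p) {
  sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Each SNP's dosage is drawn from (q^2, 2pq, p^2) at its MAF.  Pairs
#' listed in `ld_blocks` are drawn jointly from a two-locus haplotype
#' distribution whose haplotype frequency is set to hit the requested
#' r-squared.
#'
#' @param spec `sim_spec`.
#' @param n number of subjects (default from spec).
#' @param seed RNG seed (default derived from the spec seed).
#' @return A `genotype_matrix`.
#' @export
simulate_genotypes <- function(spec, n = spec$n_subjects,
                               seed = derive_seed(spec$seed, "genotypes")) {
  set.seed(seed)
  panel <- spec$panel
  dos <- matrix(NA_integer_, n, nrow(panel))
  done <- logical(nrow(panel))
  for (blk in spec$ld_blocks %||% list()) {
    i <- match(blk$snps, panel$rsid)
    if (anyNA(i) || length(i) != 2) stopf("LD block must name two panel SNPs")
    if (any(done[i])) stopf("SNP in more than one LD block")
    pA <- spec$maf[i[1]]; pB <- spec$maf[i[2]]
    r <- sqrt(blk$r2)
    pAB <- pA * pB + r * sqrt(pA * (1 - pA) * pB * (1 - pB))
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pAB <- min(max(pAB, lo), hi)
    hp <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB) # (11,10,01,00)
    h1 <- sample.int(4, n, replace = TRUE, prob = hp)
    h2 <- sample.int(4, n, replace = TRUE, prob = hp)
    dos[, i[1]] <- (h1 <= 2) + (h2 <= 2)
    dos[, i[2]] <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
    done[i] <- TRUE
  }
  for (j in which(!done)) dos[, j] <- rhwe(n, spec$maf[j])
  genotype_matrix(dos, sprintf("S%04d", seq_len(n)), panel)
}

simulate_covariates <- function(spec, n = spec$n_subjects,
                                seed = derive_seed(spec$seed, "covariates")) {
  set.seed(seed)
  cp <- spec$covariate_params
  sigma2 <- log(1 + (cp$age_sd / cp$age_mean)^2)
  mu <- log(cp$age_mean) - sigma2 / 2
  age <- stats::rlnorm(n, mu, sqrt(sigma2))
  while (any(age > cp$age_max)) { # truncate by resampling
    i <- age > cp$age_max
    age[i] <- stats::rlnorm(sum(i), mu, sqrt(sigma2))
  }
  weight <- pmax(1.5, cp$weight_intercept + cp$weight_slope * age +
                   stats::rnorm(n, 0, cp$weight_sd))
  data.frame(
    age_months = age,
    female = stats::runif(n) < cp$p_female,
    non_white = stats::runif(n) < cp$p_non_white,
    hispanic = stats::runif(n) < cp$p_hispanic,
    weight_kg = weight,
    culture_positive = stats::runif(n) < cp$p_culture,
    pdad = stats::runif(n) < cp$p_pdad,
    prm_at_6m = if (spec$timepoint == "12m") stats::runif(n) < cp$p_prm6 else NA
  )
}

# Per-subject genetic + covariate linear predictor (without intercept).
linear_predictor <- function(spec, genotypes, covariates) {
  eta <- rep(0, nrow(covariates))
  for (e in spec$effects) {
    idx <- match(e$snps, genotypes$panel$rsid)
    cls <- classify_patterns(genotypes$dosage[, idx, drop = FALSE], e$labels,
                             e$convention %||% "paper_literal")
    eta <- eta + e$log_or * ifelse(is.na(cls), 0, cls)
  }
  cb <- spec$covariate_betas
  for (v in names(cb)) {
    if (cb[[v]] == 0) next
    eta <- eta + cb[[v]] * as.numeric(covariates[[v]])
  }
  eta
}

#' Calibrate the penetrance-model intercept to a target prevalence
#'
#' Root-finds the intercept so that the population-average case
#' probability equals the spec's target prevalence to within 1e-4,
#' averaging over a large reference population simulated from the spec.
#' With no planted effects and zero covariate betas this reduces to the
#' closed form `qlogis(target)`.
#'
#' @param spec `sim_spec`.
#' @param n_ref reference population size (default 50000).
#' @return The intercept `beta0` (log-odds scale).
#' @export
calibrate_intercept <- function(spec, n_ref = 50000) {
  if (!length(spec$effects) && all(spec$covariate_betas == 0))
    return(stats::qlogis(spec$target_prevalence))
  g <- simulate_genotypes(spec, n = n_ref, seed = derive_seed(spec$seed, "calib_g"))
  cv <- simulate_covariates(spec, n = n_ref, seed = derive_seed(spec$seed, "calib_c"))
  eta <- linear_predictor(spec, g, cv)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - spec$target_prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stopf("intercept calibration bracket failure")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Draw case status from the logistic penetrance model
#'
#' `logit P(case) = beta0 + sum(log_or * selected-group indicator) +
#' sum(covariate betas)`, Bernoulli per subject.
#'
#' @param spec `sim_spec`.
#' @param genotypes `genotype_matrix`.
#' @param covariates covariate data frame.
#' @param beta0 calibrated intercept (default [calibrate_intercept()]).
#' @param seed RNG seed.
#' @return list with `status` (0/1) and `truth` (beta0, per-subject
#'   linear predictor and case probability, planted effects).
#' @export
simulate_status <- function(spec, genotypes, covariates,
                            beta0 = calibrate_intercept(spec),
                            seed = derive_seed(spec$seed, "status")) {
  set.seed(seed)
  eta <- linear_predictor(spec, genotypes, covariates)
  prob <- stats::plogis(beta0 + eta)
  status <- stats::rbinom(length(prob), 1, prob)
  list(status = status,
       truth = list(beta0 = beta0, eta = eta, prob = prob,
                    effects = spec$effects))
}

#' Inject missing genotypes completely at random
#'
#' @param genotypes `genotype_matrix`.
#' @param rate per-cell dropout probability in [0,1).
#' @param seed RNG seed.
#' @return A `genotype_matrix` with missing cells.
#' @export
inject_missing <- function(genotypes, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0,1)")
  if (rate == 0) return(genotypes)
  set.seed(seed)
  d <- genotypes$dosage
  d[stats::runif(length(d)) < rate] <- NA_integer_
  genotype_matrix(d, genotypes$subject_ids, genotypes$panel)
}

#' Simulate a complete case-control cohort
#'
#' Orchestrates [simulate_genotypes()], covariate generation, intercept
#' calibration, [simulate_status()] and [inject_missing()] under seeds
#' derived from the spec seed, so the same spec reproduces the cohort
#' bit-identically.
#'
#' @param spec `sim_spec`.
#' @return list with `genotypes` (`genotype_matrix`), `cohort`
#'   (`cohort_table`) and `truth`.
#' @export
simulate_cohort <- function(spec) {
  g <- simulate_genotypes(spec)
  cv <- simulate_covariates(spec)
  st <- simulate_status(spec, g, cv)
  g <- inject_missing(g, spec$missing_rate, seed = derive_seed(spec$seed, "missing"))
  cohort <- cohort_table(data.frame(subject_id = g$subject_ids,
                                    timepoint = spec$timepoint,
                                    status = st$status, cv,
                                    stringsAsFactors = FALSE))
  list(genotypes = g, cohort = cohort, truth = st$truth)
}

# Locate a planted effect's row in a sweep family: subsets are enumerated
# in panel order, so reorder the effect's SNPs/labels accordingly.
locate_effect <- function(all_tests, panel, effect) {
  idx <- match(effect$snps, panel$rsid)
  o <- order(idx)
  et <- format(effect_type(effect$labels[o]))
  k <- length(idx)
  hit <- all_tests$effect_type == et
  for (j in seq_len(k))
    hit <- hit & all_tests[[paste0("snp", j)]] == panel$rsid[sort(idx)][j]
  which(hit)
}

#' Power and familywise error study over simulation specs
#'
#' For each spec, simulates `reps` cohorts and runs the k-SNP interaction
#' sweep.  Specs with planted effects yield the power to detect the first
#' planted effect at BH FDR `q` and the mean recovered log Mantel-Haenszel
#' OR; specs without effects yield the familywise any-BH-discovery rate.
#'
#' @param specs named list of `sim_spec`s.
#' @param reps simulated cohorts per spec.
#' @param q FDR level (default 0.05).
#' @param k model order for the sweep (default 2).
#' @param convention grouping convention for the sweep.
#' @return data.frame with one row per spec: `scenario`, `n`, `reps`,
#'   `power`, `mean_log_or`, `any_discovery_rate`.
#' @export
power_study <- function(specs, reps = 100, q = 0.05, k = 2,
                        convention = "paper_literal") {
  rows <- lapply(seq_along(specs), function(s) {
    spec <- specs[[s]]
    hits <- logical(reps); any_disc <- logical(reps)
    logor <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      spec_r <- spec
      spec_r$seed <- derive_seed(spec$seed, paste0("rep", s, "_", r))
      sim <- simulate_cohort(spec_r)
      res <- run_model(k, sim$genotypes, sim$cohort, convention = convention,
                       fdr_q = q)
      fam <- attr(res, "all_tests")
      any_disc[r] <- any(fam$significant_fdr, na.rm = TRUE)
      if (length(spec$effects)) {
        i <- locate_effect(fam, spec$panel, spec$effects[[1]])
        if (length(i) == 1) {
          hits[r] <- isTRUE(fam$significant_fdr[i])
          logor[r] <- log(fam$or_mh[i])
        }
      }
    }
    data.frame(scenario = names(specs)[s] %||% as.character(s),
               n = spec$n_subjects, reps = reps,
               power = if (length(spec$effects)) mean(hits) else NA_real_,
               mean_log_or = if (length(spec$effects))
                 mean(logor[is.finite(logor)]) else NA_real_,
               any_discovery_rate = mean(any_disc))
  })
  do.call(rbind, rows)
}
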