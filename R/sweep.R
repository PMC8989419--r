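# Vectorised Mantel-Haenszel machinery shared by cmh_estimate() and the
# interaction sweep: a,b,c,d are per-stratum cell counts (case-selected,
# case-complement, control-selected, control-complement).
cmh_from_counts <- function(a, b, c_, d, correct = FALSE, quiet = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  ok <- (a + b) > 0 & (c_ + d) > 0 & (a + c_) > 0 & (b + d) > 0 & n > 1
  if (any(!ok) && !quiet)
    log_note("cmh_estimate: dropping ", sum(!ok), " stratum/strata with zero margins")
  if (!any(ok)) return(NULL)
  a <- a[ok]; b <- b[ok]; c_ <- c_[ok]; d <- d[ok]; n <- n[ok]
  R <- a * d / n; S <- b * c_ / n
  sumR <- sum(R); sumS <- sum(S)
  or <- if (sumS == 0) Inf else if (sumR == 0) 0 else sumR / sumS
  P <- (a + d) / n; Q <- (b + c_) / n
  var_log <- if (sumR > 0 && sumS > 0)
    sum(P * R) / (2 * sumR^2) + sum(P * S + Q * R) / (2 * sumR * sumS) +
      sum(Q * S) / (2 * sumS^2) else NA_real_
  ci <- if (is.finite(or) && or > 0 && !is.na(var_log))
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_log))
  else c(NA_real_, NA_real_)
  r1 <- a + b; c1 <- a + c_
  Vs <- sum(r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1)))
  p <- if (Vs > 0)
    stats::pchisq((abs(sum(a - r1 * c1 / n)) - if (correct) 0.5 else 0)^2 / Vs,
                  df = 1, lower.tail = FALSE) else NA_real_
  list(or_mh = unname(or), ci95 = ci, p_cmh = p, n_strata_used = length(n))
}

#' Sweep all SNP subsets and effect types of a k-SNP interaction model
#'
#' The central computation: for every subset of `k` panel SNPs and every
#' non-silent additive/dominant effect type, subjects are partitioned
#' into the selected genotype group versus the remaining genotypes,
#' sorted into case-control 2x2 tables within covariate strata, and the
#' effect is quantified by the Mantel-Haenszel pooled odds ratio
#' (Robins-Breslow-Greenland 95% CI) together with a covariate-adjusted
#' logistic Wald p-value (age, sex, race, weight).  Benjamini-Hochberg
#' q-values are computed over the whole k-SNP family; records with an
#' adjusted p-value below `report_threshold` are returned.  Individual
#' degenerate tests (constant indicator, separation, non-convergence)
#' are flagged and skipped, never abort the sweep.
#'
#' @param k model order: 1, 2 or 3 SNPs.
#' @param genotypes `genotype_matrix`.
#' @param cohort `cohort_table` for one timepoint, aligned by subject id.
#' @param convention genotype-grouping convention, see
#'   [partition_genotypes()].
#' @param report_threshold report tests with adjusted p below this
#'   (default 0.05).
#' @param fdr_q FDR level for the significance flag (default 0.05).
#' @param strata optional stratum factor; defaults to
#'   [stratify_covariates()].
#' @param correct_cmh continuity-correct the CMH statistic.
#' @return data.frame of reported association records sorted by
#'   (adjusted p, OR), with attributes `all_tests` (the full family,
#'   unfiltered) and `n_tests`.  Columns: snp1..snpk, gene1..genek,
#'   effect_type, n_used, or_mh, or_mh_low, or_mh_high, p_cmh, or_adj,
#'   or_adj_low, or_adj_high, p_adj, fdr_q, significant_fdr, direction,
#'   flag.
#' @export
run_model <- function(k, genotypes, cohort,
                      convention = c("paper_literal", "orthogonal"),
                      report_threshold = 0.05, fdr_q = 0.05,
                      strata = NULL, correct_cmh = FALSE) {
  convention <- match.arg(convention)
  if (!k %in% 1:3) stopf("k must be 1, 2 or 3")
  ord <- match(cohort$subject_id, genotypes$subject_ids)
  if (anyNA(ord)) stopf("cohort subject ids missing from genotype matrix")
  D <- genotypes$dosage[ord, , drop = FALSE]
  y <- cohort$status
  if (is.null(strata)) strata <- stratify_covariates(cohort)
  sid <- as.integer(strata)
  K <- nlevels(strata)
  X0 <- cbind(1, cohort$age_months, as.numeric(cohort$female),
              as.numeric(cohort$non_white), cohort$weight_kg)
  cc0 <- stats::complete.cases(X0) & !is.na(y)
  types <- enumerate_effect_types(k)
  type_str <- vapply(types, format, character(1))
  subsets <- utils::combn(ncol(D), k)
  n_tests <- ncol(subsets) * length(types)
  res <- vector("list", n_tests)
  r <- 0L
  panel <- genotypes$panel
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    Ds <- D[, cols, drop = FALSE]
    for (t in seq_along(types)) {
      r <- r + 1L
      ind <- classify_patterns(Ds, types[[t]]$labels, convention)
      use <- !is.na(ind) & !is.na(y)
      rec <- list(snps = panel$rsid[cols], genes = panel$gene[cols],
                  effect_type = type_str[t])
      if (!any(use) || length(unique(ind[use])) < 2) {
        res[[r]] <- c(rec, list(n_used = sum(use), or_mh = NA_real_,
                                or_low = NA_real_, or_high = NA_real_, p_cmh = NA_real_,
                                or_adj = NA_real_, adj_low = NA_real_, adj_high = NA_real_,
                                p_adj = NA_real_, flag = "constant_indicator"))
        next
      }
      code <- (sid[use] - 1L) * 4L + y[use] * 2L + ind[use] + 1L
      cnt <- tabulate(code, nbins = 4L * K)
      dim(cnt) <- c(4L, K)
      cmh <- cmh_from_counts(cnt[4, ], cnt[3, ], cnt[2, ], cnt[1, ],
                             correct = correct_cmh, quiet = TRUE)
      if (is.null(cmh))
        cmh <- list(or_mh = NA_real_, ci95 = c(NA_real_, NA_real_),
                    p_cmh = NA_real_, n_strata_used = 0L)
      use2 <- use & cc0
      flag <- ""
      wald <- c(NA_real_, NA_real_, NA_real_)
      if (sum(use2) && length(unique(ind[use2])) == 2)
        wald <- logistic_wald_last(cbind(X0[use2, , drop = FALSE], ind[use2]), y[use2])
      else flag <- "constant_indicator"
      if (flag == "" && is.na(wald[3])) flag <- "non_estimable"
      res[[r]] <- c(rec, list(
        n_used = sum(use), or_mh = cmh$or_mh, or_low = cmh$ci95[1],
        or_high = cmh$ci95[2], p_cmh = cmh$p_cmh,
        or_adj = unname(exp(wald[1])),
        adj_low = unname(exp(wald[1] - stats::qnorm(0.975) * wald[2])),
        adj_high = unname(exp(wald[1] + stats::qnorm(0.975) * wald[2])),
        p_adj = unname(wald[3]), flag = flag))
    }
  }
  all_tests <- assemble_records(res, k)
  fdr <- bh_fdr(all_tests$p_adj, q = fdr_q)
  all_tests$fdr_q <- fdr$q_values
  all_tests$significant_fdr <- fdr$significant
  all_tests$direction <- ifelse(is.na(all_tests$or_mh), NA_character_,
                                ifelse(all_tests$or_mh > 1, "risk", "protective"))
  keep <- !is.na(all_tests$p_adj) & all_tests$p_adj < report_threshold
  records <- all_tests[keep, , drop = FALSE]
  records <- records[order(records$p_adj, records$or_mh), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, all_tests = all_tests, n_tests = n_tests,
            convention = convention, k = k,
            class = c("epistasis_records", "data.frame"))
}

assemble_records <- function(res, k) {
  snp_cols <- lapply(seq_len(k), function(j)
    vapply(res, function(x) x$snps[j], character(1)))
  gene_cols <- lapply(seq_len(k), function(j)
    vapply(res, function(x) x$genes[j], character(1)))
  names(snp_cols) <- paste0("snp", seq_len(k))
  names(gene_cols) <- paste0("gene", seq_len(k))
  num <- function(f) vapply(res, function(x) as.numeric(x[[f]]), numeric(1))
  out <- data.frame(snp_cols, gene_cols,
                    effect_type = vapply(res, `[[`, character(1), "effect_type"),
                    n_used = num("n_used"),
                    or_mh = num("or_mh"), or_mh_low = num("or_low"),
                    or_mh_high = num("or_high"), p_cmh = num("p_cmh"),
                    or_adj = num("or_adj"), or_adj_low = num("adj_low"),
                    or_adj_high = num("adj_high"), p_adj = num("p_adj"),
                    flag = vapply(res, `[[`, character(1), "flag"),
                    stringsAsFactors = FALSE)
  out
}

#' @export
print.epistasis_records <- function(x, ...) {
  cat(sprintf("%d-SNP interaction sweep (%s convention): %d tests, %d reported, %d FDR-significant\n",
              attr(x, "k"), attr(x, "convention"), attr(x, "n_tests"),
              nrow(x), sum(x$significant_fdr, na.rm = TRUE)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20), row.names = FALSE)
  invisible(x)
}
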