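#' Minor-allele counts by case status
#'
#' Tallies the minor allele among non-missing genotypes, split by
#' case/control group: allele count, total alleles (twice the non-missing
#' subjects) and the percentage of possible alleles.
#'
#' @param genotypes `genotype_matrix`.
#' @param cohort `cohort_table` aligned to the genotype matrix.
#' @param rsid SNP to tabulate (must be in the panel).
#' @return data.frame with rows `case` and `control` and columns
#'   `minor_count`, `total_alleles`, `percent`.
#' @export
allele_counts <- function(genotypes, cohort, rsid) {
  if (!rsid %in% genotypes$panel$rsid) stopf("%s is not in the panel", rsid)
  d <- genotypes$dosage[match(cohort$subject_id, genotypes$subject_ids), rsid]
  out <- do.call(rbind, lapply(c(case = 1L, control = 0L), function(s) {
    di <- d[cohort$status == s & !is.na(d)]
    n2 <- 2L * length(di)
    cnt <- sum(di)
    data.frame(minor_count = cnt, total_alleles = n2,
               percent = if (n2 > 0) 100 * cnt / n2 else NA_real_)
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[c("group", "minor_count", "total_alleles", "percent")]
}

#' Exact (or chi-square) Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed minor-allele count, the
#' p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one.  A chi-square (1 df) alternative is
#' available via `method = "chisq"`.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # most probable configuration: p = 1
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor,
                           method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) stopf("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stopf("no genotypes observed")
  if (method == "chisq") {
    p <- (2 * n_hom_minor + n_het) / (2 * n)
    if (p %in% c(0, 1)) return(1)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((counts - e)^2 / e)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  probs <- hwe_het_distribution(n, 2 * n_hom_minor + n_het)
  obs <- probs$p[match(n_het, probs$het)]
  if (is.na(obs)) stopf("heterozygote count inconsistent with allele count")
  min(1, sum(probs$p[probs$p <= obs * (1 + 1e-7)]))
}

# Distribution of the heterozygote count conditional on n subjects and
# n_minor minor alleles: P(h) = n! 2^h / (h_AA! h! h_aa!) / choose(2n, n_minor).
hwe_het_distribution <- function(n, n_minor) {
  n_minor <- min(n_minor, 2 * n - n_minor) # symmetric; work with rarer allele
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(hom_maj) - lfactorial(h) - lfactorial(hom_min) +
      h * log(2) - lchoose(2 * n, n_minor)
  }, numeric(1))
  p <- exp(lp)
  list(het = hets, p = p / sum(p))
}

#' Per-SNP QC summary
#'
#' Minor-allele frequency, genotype counts, missingness and the HWE exact
#' p-value for every panel SNP, computed over the whole sample (or a
#' subgroup).
#'
#' @param genotypes `genotype_matrix`.
#' @param subset optional logical vector of subjects to keep.
#' @param method HWE test variant, see [hwe_exact_test()].
#' @return data.frame, one row per SNP.
#' @export
qc_snps <- function(genotypes, subset = NULL, method = "exact") {
  d <- genotypes$dosage
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  res <- lapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]
    n0 <- sum(v == 0L, na.rm = TRUE); n1 <- sum(v == 1L, na.rm = TRUE)
    n2 <- sum(v == 2L, na.rm = TRUE)
    n <- n0 + n1 + n2
    data.frame(rsid = genotypes$panel$rsid[j], gene = genotypes$panel$gene[j],
               n = n, n_missing = sum(is.na(v)),
               maf = if (n > 0) (2 * n2 + n1) / (2 * n) else NA_real_,
               n_hom_major = n0, n_het = n1, n_hom_minor = n2,
               hwe_p = if (n > 0) hwe_exact_test(n0, n1, n2, method) else NA_real_)
  })
  do.call(rbind, res)
}
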