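#' Effect types: additive/dominant/silent labels over a SNP subset
#'
#' An effect type assigns each SNP in a 1-, 2- or 3-SNP model one of the
#' labels additive (`"a"`), dominant (`"d"`) or `"silent"`.  Its string
#' form concatenates the letter and 1-based SNP position for the
#' non-silent entries, e.g. `c("a","silent","d")` prints as `"a1d3"`.
#'
#' @param labels character vector (length 1-3) over
#'   `c("a","d","silent")`; at least one non-silent entry.
#' @return An `effect_type` object.
#' @export
effect_type <- function(labels) {
  if (!length(labels) %in% 1:3) stopf("effect type length must be 1, 2 or 3")
  if (!all(labels %in% c("a", "d", "silent"))) stopf("labels must be 'a', 'd' or 'silent'")
  if (all(labels == "silent")) stopf("effect type cannot be all silent")
  structure(list(labels = labels), class = "effect_type")
}

#' @export
format.effect_type <- function(x, ...) {
  i <- which(x$labels != "silent")
  paste0(x$labels[i], i, collapse = "")
}

#' @export
print.effect_type <- function(x, ...) {
  cat("effect type:", format(x), sprintf("(k = %d)\n", length(x$labels)))
  invisible(x)
}

# Parse an effect-type string like "a1d3" back into a label vector of
# length k (inverse of format.effect_type).
type_labels_from_string <- function(s, k) {
  lab <- rep("silent", k)
  m <- regmatches(s, gregexpr("[ad][123]", s))[[1]]
  if (!length(m) || nchar(s) != 2 * length(m))
    stopf("malformed effect-type string: %s", s)
  for (tok in m) {
    pos <- as.integer(substr(tok, 2, 2))
    if (pos > k) stopf("effect-type position %d exceeds k = %d", pos, k)
    lab[pos] <- substr(tok, 1, 1)
  }
  lab
}

#' Enumerate all effect types for a k-SNP model
#'
#' Yields all `3^k - 1` label assignments (every SNP additive, dominant
#' or silent; not all silent) in a deterministic order: main effects
#' first, then higher-order combinations, positions in increasing order
#' and `a` before `d` within a position set.  For k = 2 this is
#' a1, d1, a2, d2, a1a2, a1d2, d1a2, d1d2.
#'
#' @param k number of SNPs in the model (1, 2 or 3).
#' @return List of [effect_type()] objects.
#' @export
enumerate_effect_types <- function(k) {
  if (!k %in% 1:3) stopf("k must be 1, 2 or 3")
  out <- list()
  positions <- seq_len(k)
  subsets <- unlist(lapply(positions, function(m)
    utils::combn(positions, m, simplify = FALSE)), recursive = FALSE)
  subsets <- subsets[order(lengths(subsets))]
  for (S in subsets) {
    grids <- expand.grid(rep(list(c("a", "d")), length(S)),
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    # vary the last position fastest so a... blocks precede d... blocks
    grids <- grids[do.call(order, as.list(grids)), , drop = FALSE]
    for (r in seq_len(nrow(grids))) {
      lab <- rep("silent", k)
      lab[S] <- unlist(grids[r, ], use.names = FALSE)
      out[[length(out) + 1L]] <- effect_type(lab)
    }
  }
  out
}

# zygosity codes: 0 = major-allele homozygote, 1 = heterozygote,
# 2 = minor-allele homozygote (equal to minor-allele dosage).
.zyg_codes <- 0:2

zygosity_label <- function(codes) {
  # locus 1 -> A/a, locus 2 -> B/b, locus 3 -> C/c
  paste0(vapply(seq_along(codes), function(i) {
    up <- LETTERS[i]; lo <- letters[i]
    switch(codes[i] + 1L, paste0(up, up), paste0(up, lo), paste0(lo, lo))
  }, character(1)), collapse = "")
}

#' Partition multi-locus genotypes for an effect type
#'
#' Under the default `paper_literal` convention the selected group
#' consists of every multi-locus genotype in which each additive-labelled
#' SNP is homozygous (either homozygote), each dominant-labelled SNP is
#' heterozygous and silent SNPs are unconstrained; the complement is every
#' remaining genotype.  E.g. for a1d2 the selected group is {AABb, aaBb}
#' and the complement the seven other two-locus genotypes.  Under the
#' `orthogonal` convention additive-labelled SNPs contrast minor-allele
#' homozygotes against major-allele homozygotes (heterozygotes at such a
#' SNP are excluded from the test) and dominant-labelled SNPs contrast
#' heterozygotes against pooled homozygotes.
#'
#' @param et [effect_type()].
#' @param convention `"paper_literal"` or `"orthogonal"`.
#' @return list with integer pattern matrices `selected`, `complement`,
#'   `excluded` (k columns of zygosity codes 0/1/2), character-label
#'   versions `selected_labels` / `complement_labels`, and the inputs.
#' @export
partition_genotypes <- function(et, convention = c("paper_literal", "orthogonal")) {
  convention <- match.arg(convention)
  k <- length(et$labels)
  grid <- as.matrix(expand.grid(rep(list(.zyg_codes), k),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  colnames(grid) <- paste0("locus", seq_len(k))
  cls <- classify_patterns(grid, et$labels, convention)
  out <- list(selected = grid[which(cls == 1L), , drop = FALSE],
              complement = grid[which(cls == 0L), , drop = FALSE],
              excluded = grid[which(is.na(cls)), , drop = FALSE],
              effect_type = et, convention = convention)
  out$selected_labels <- apply(out$selected, 1, zygosity_label)
  out$complement_labels <- apply(out$complement, 1, zygosity_label)
  out
}

# Vectorised classification of zygosity-code rows: 1 selected,
# 0 complement, NA excluded.  Shared by partition_genotypes() and the
# sweep fast path so the two can never disagree.
classify_patterns <- function(codes, labels, convention) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  sel <- rep(TRUE, n)
  excl <- rep(FALSE, n)
  for (j in seq_along(labels)) {
    v <- codes[, j]
    excl <- excl | is.na(v)
    if (labels[j] == "a") {
      if (convention == "paper_literal") {
        sel <- sel & v != 1L
      } else {
        excl <- excl | (!is.na(v) & v == 1L)
        sel <- sel & v == 2L
      }
    } else if (labels[j] == "d") {
      sel <- sel & v == 1L
    }
  }
  out <- as.integer(sel)
  out[excl] <- NA_integer_
  out
}

#' Assign subjects to the selected/complement groups of a partition
#'
#' Subjects with any missing genotype at the tested SNPs are excluded
#' (pairwise deletion; genotypes are never imputed), as are subjects in
#' zygosity classes the convention drops.
#'
#' @param partition from [partition_genotypes()].
#' @param genotypes `genotype_matrix`.
#' @param rsids SNPs the partition applies to, in effect-type order.
#' @return factor with levels selected/complement/excluded, one per
#'   subject.
#' @export
assign_subjects <- function(partition, genotypes, rsids) {
  if (!all(rsids %in% genotypes$panel$rsid)) stopf("rsid(s) not in panel")
  if (length(rsids) != length(partition$effect_type$labels))
    stopf("number of SNPs does not match the effect type")
  D <- genotypes$dosage[, rsids, drop = FALSE]
  cls <- classify_patterns(D, partition$effect_type$labels, partition$convention)
  factor(ifelse(is.na(cls), "excluded", ifelse(cls == 1L, "selected", "complement")),
         levels = c("selected", "complement", "excluded"))
}

#' Build the case-control 2x2 table for a group assignment
#'
#' Rows are case/control, columns selected/complement; excluded subjects
#' are omitted.
#'
#' @param status 0/1 case status per subject.
#' @param assignment factor from [assign_subjects()].
#' @return 2x2 integer matrix with dimnames.
#' @export
build_2x2 <- function(status, assignment) {
  keep <- assignment != "excluded" & !is.na(status)
  if (!any(keep)) stopf("all subjects excluded")
  y <- status[keep]; g <- assignment[keep]
  if (length(unique(y)) < 2) stopf("both case and control statuses required")
  tab <- matrix(c(sum(y == 1 & g == "selected"), sum(y == 1 & g == "complement"),
                  sum(y == 0 & g == "selected"), sum(y == 0 & g == "complement")),
                2, 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("selected", "complement")))
  tab
}

#' Covariate strata for the Mantel-Haenszel analysis
#'
#' Default scheme: sex x race (White / non-White) x age split at the
#' cohort median (ages at or below the median are "young"), eight strata.
#' Weight stays out of the stratification and is handled in the logistic
#' adjustment instead, since age and weight are strongly collinear in
#' infants.  Subjects missing any stratification covariate form their own
#' "missing" stratum.
#'
#' @param cohort `cohort_table`.
#' @param scheme currently only `"sex_race_age"`.
#' @return factor of stratum labels, one per subject.
#' @export
stratify_covariates <- function(cohort, scheme = "sex_race_age") {
  if (scheme != "sex_race_age") stopf("unknown stratification scheme: %s", scheme)
  med <- stats::median(cohort$age_months, na.rm = TRUE)
  young <- cohort$age_months <= med
  lab <- paste0(ifelse(cohort$female, "F", "M"), ".",
                ifelse(cohort$non_white, "nonwhite", "white"), ".",
                ifelse(young, "young", "old"))
  lab[is.na(cohort$female) | is.na(cohort$non_white) | is.na(young)] <- "missing"
  factor(lab)
}

#' Mantel-Haenszel pooled odds ratio over covariate strata
#'
#' Computes the Mantel-Haenszel common odds ratio
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over 2x2 tables, the
#' Robins-Breslow-Greenland standard error for its 95% confidence
#' interval, and the Cochran-Mantel-Haenszel chi-square p-value (1 df,
#' optional continuity correction).  Strata with a zero row or column
#' margin are dropped with a log entry; zero cells need no correction
#' under the MH estimator.
#'
#' @param tables list of 2x2 matrices (rows case/control, columns
#'   selected/complement), one per stratum.
#' @param correct continuity-correct the CMH statistic (default FALSE).
#' @return list with `or_mh`, `ci95`, `p_cmh`, `n_strata_used`.
#' @export
cmh_estimate <- function(tables, correct = FALSE) {
  if (is.array(tables) && length(dim(tables)) == 3)
    tables <- lapply(seq_len(dim(tables)[3]), function(i) tables[, , i])
  if (is.matrix(tables)) tables <- list(tables)
  if (any(vapply(tables, function(t) !all(dim(t) == 2), logical(1))))
    stopf("each stratum must be a 2x2 table")
  a <- vapply(tables, function(t) t[1, 1], numeric(1))
  b <- vapply(tables, function(t) t[1, 2], numeric(1))
  c_ <- vapply(tables, function(t) t[2, 1], numeric(1))
  d <- vapply(tables, function(t) t[2, 2], numeric(1))
  out <- cmh_from_counts(a, b, c_, d, correct = correct)
  if (is.null(out)) stopf("all strata degenerate")
  out
}

# Fast logistic Wald test for the last design column.  Uses stats::glm.fit
# (the base IRLS engine) and recovers the coefficient covariance from the
# working weights; returns c(estimate, se, p) or NAs on failure.
logistic_wald_last <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients))
    return(c(NA_real_, NA_real_, NA_real_))
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(V)) return(c(NA_real_, NA_real_, NA_real_))
  j <- ncol(X)
  est <- fit$coefficients[j]; se <- sqrt(V[j, j])
  if (!is.finite(se) || se > 100 || abs(est) > 15)
    return(c(est, NA_real_, NA_real_)) # quasi-separation: p unreliable
  c(est, se, 2 * stats::pnorm(-abs(est / se)))
}

#' Covariate-adjusted logistic p-value for a genotype-group indicator
#'
#' Two-sided Wald p-value for the selected-group indicator in a logistic
#' model adjusting for age, sex, race and weight.  Non-convergence,
#' separation or collinearity yields a flagged record with a missing
#' p-value.
#'
#' @param status 0/1 case status.
#' @param indicator 0/1 selected-group membership (NA = excluded).
#' @param covariates data.frame with `age_months`, `female`, `non_white`,
#'   `weight_kg`.
#' @return list with `p`, `or`, `ci95`, `flag` (NA-p reason or "").
#' @export
adjusted_logistic_p <- function(status, indicator, covariates) {
  X0 <- cbind(1, covariates$age_months, as.numeric(covariates$female),
              as.numeric(covariates$non_white), covariates$weight_kg)
  ok <- !is.na(indicator) & !is.na(status) & stats::complete.cases(X0)
  # zero-variance covariates carry no adjustment information; drop them so
  # the model stays full-rank (it then reduces to the univariate test)
  keep <- c(TRUE, apply(X0[ok, -1, drop = FALSE], 2, stats::var) > 0)
  X0 <- X0[, keep, drop = FALSE]
  x <- indicator[ok]
  if (length(unique(x)) < 2) {
    log_note("adjusted_logistic_p: indicator constant after exclusions")
    return(list(p = NA_real_, or = NA_real_, ci95 = c(NA_real_, NA_real_),
                flag = "constant_indicator"))
  }
  res <- logistic_wald_last(cbind(X0[ok, , drop = FALSE], x), status[ok])
  if (is.na(res[3]))
    return(list(p = NA_real_, or = unname(exp(res[1])),
                ci95 = c(NA_real_, NA_real_), flag = "non_estimable"))
  list(p = unname(res[3]), or = unname(exp(res[1])),
       ci95 = unname(exp(res[1] + c(-1, 1) * stats::qnorm(0.975) * res[2])),
       flag = "")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values (via [stats::p.adjust()]) and significance flags at
#' the requested FDR level.  Missing p-values get missing q-values and
#' are never flagged.
#'
#' @param pvalues numeric vector of p-values (NA allowed).
#' @param q FDR level, default 0.05.
#' @return list with `q_values` and logical `significant`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(q_values = numeric(), significant = logical()))
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(q_values = qv, significant = !is.na(qv) & qv <= q)
}
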