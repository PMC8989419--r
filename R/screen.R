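#' Case-control group comparison with the chi-square/Fisher switching rule
#'
#' A 2x2 table is compared with the Yates-corrected chi-square test unless
#' any expected cell count falls below 5, in which case the two-sided
#' Fisher exact test is used.  The uncorrected chi-square is available via
#' `correct = FALSE`.
#'
#' @param tab 2x2 matrix of non-negative counts (rows: case/control,
#'   columns: exposed/unexposed).
#' @param correct apply Yates continuity correction on the chi-square
#'   branch (default TRUE).
#' @return list with `p_value`, `test_used` ("chi2_yates", "chi2" or
#'   "fisher") and `statistic` (NA on the Fisher branch).
#' @export
group_compare_p <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stopf("group_compare_p expects a 2x2 table")
  if (any(tab < 0)) stopf("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero-margin table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(p_value = ft$p.value, test_used = "fisher", statistic = NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(p_value = ct$p.value,
         test_used = if (correct) "chi2_yates" else "chi2",
         statistic = unname(ct$statistic))
  }
}

#' Carrier indicator under the no-dose-effect model
#'
#' Maps minor-allele dosage to carriage of at least one minor allele:
#' 0 -> 0, 1 or 2 -> 1, NA propagates.
#'
#' @param dosage integer vector in `{0,1,2,NA}`.
#' @return Integer vector in `{0,1,NA}`.
#' @export
carrier_indicator <- function(dosage) {
  out <- ifelse(is.na(dosage), NA_integer_, as.integer(dosage > 0))
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) stopf("dosage out of {0,1,2,NA}")
  out
}

wald_summary <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) return(NULL)
  est <- sm[term, 1]; se <- sm[term, 2]
  list(or = exp(est), ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
       p = sm[term, 4], log_or = est, se = se)
}

#' Univariate logistic regression of case status on a binary predictor
#'
#' Returns the odds ratio with a Wald 95% interval and two-sided Wald
#' p-value.  Perfect separation (a zero cell in the 2x2 table) is flagged;
#' the record then carries an infinite (or zero) odds-ratio sentinel and a
#' Fisher-exact fallback p-value.
#'
#' @param status 0/1 case status.
#' @param predictor 0/1 exposure; NA pairs are dropped.
#' @return list with `or`, `ci95`, `p`, `separation` (logical), `n`.
#' @export
univariate_logistic <- function(status, predictor) {
  ok <- !is.na(status) & !is.na(predictor)
  y <- status[ok]; x <- predictor[ok]
  if (length(unique(y)) < 2) stopf("both case and control statuses required")
  if (length(unique(x)) < 2) stopf("predictor is constant")
  if (all(x %in% c(0, 1))) {
    tab <- matrix(c(sum(y == 1 & x == 1), sum(y == 1 & x == 0),
                    sum(y == 0 & x == 1), sum(y == 0 & x == 0)),
                  2, 2, byrow = TRUE)
    if (any(tab == 0)) {
      log_note("univariate_logistic: perfect separation / empty cell; Fisher fallback")
      or <- if (tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]) Inf else 0
      return(list(or = or, ci95 = c(NA_real_, NA_real_),
                  p = stats::fisher.test(tab)$p.value,
                  separation = TRUE, n = length(y)))
    }
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  ws <- wald_summary(fit, "x")
  c(list(or = ws$or, ci95 = ws$ci95, p = ws$p,
         separation = !fit$converged || abs(ws$log_or) > 15),
    n = length(y))
}

#' Select screening candidates at a relaxed threshold
#'
#' Keeps records whose univariate p-value is strictly below `alpha`
#' (default 0.1), preserving input order.  These are the terms offered to
#' the multivariate model.
#'
#' @param records data.frame with a `p` column (one row per tested term).
#' @param alpha screening threshold, default 0.1.
#' @return The subset of `records` with `p < alpha`.
#' @export
screen_candidates <- function(records, alpha = 0.1) {
  if (NROW(records) == 0) return(records)
  records[!is.na(records$p) & records$p < alpha, , drop = FALSE]
}

#' Multivariate logistic regression with backward elimination
#'
#' Refits repeatedly, removing the non-obliged term with the largest Wald
#' p-value while that p-value exceeds `alpha` (default 0.05).  Obliged
#' terms are never removed.  Ties on the largest p are broken by removing
#' the later column.  Complete-case analysis over the supplied columns.
#'
#' @param status 0/1 case status.
#' @param candidates data.frame or matrix of candidate predictors (named
#'   columns).
#' @param obliged character vector of column names that must stay in the
#'   model.
#' @param alpha elimination threshold, default 0.05.
#' @return list with `terms` (retained names), `summary` (data.frame of
#'   term, or, ci_low, ci_high, p), `removed` (in removal order) and
#'   `fit` (the final `glm`).
#' @export
multivariate_backward <- function(status, candidates, obliged = character(), alpha = 0.05) {
  X <- as.data.frame(candidates)
  if (!ncol(X)) stopf("no candidate predictors")
  if (!all(obliged %in% names(X))) stopf("obliged term(s) missing from candidates")
  ok <- stats::complete.cases(X) & !is.na(status)
  y <- status[ok]; X <- X[ok, , drop = FALSE]
  keep <- names(X)
  removed <- character()
  repeat {
    dat <- cbind(y = y, X[keep])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (anyNA(fit$coefficients[paste0("`", obliged, "`") %in% names(fit$coefficients)]))
      stopf("obliged term not estimable")
    rn <- rownames(co)
    term_of <- function(nm) gsub("`", "", nm)
    drop_pool <- setdiff(keep, obliged)
    if (anyNA(fit$coefficients)) {
      na_terms <- term_of(names(fit$coefficients)[is.na(fit$coefficients)])
      if (any(na_terms %in% obliged)) stopf("obliged term not estimable (collinear)")
      victim <- intersect(rev(keep), na_terms)[1]
      log_note("multivariate_backward: dropping non-estimable term ", victim)
    } else {
      pvals <- co[match(paste0("`", drop_pool, "`"), rn), 4]
      pvals[is.na(pvals)] <- co[match(drop_pool, rn), 4][is.na(pvals)]
      if (!length(drop_pool) || all(pvals <= alpha, na.rm = TRUE)) {
        sm <- do.call(rbind, lapply(keep, function(tm) {
          ws <- wald_summary(fit, if (paste0("`", tm, "`") %in% rn) paste0("`", tm, "`") else tm)
          data.frame(term = tm, or = ws$or, ci_low = ws$ci95[1],
                     ci_high = ws$ci95[2], p = ws$p)
        }))
        return(list(terms = keep, summary = sm, removed = removed, fit = fit))
      }
      worst <- max(pvals, na.rm = TRUE)
      victim <- drop_pool[max(which(pvals == worst))]
    }
    keep <- setdiff(keep, victim)
    removed <- c(removed, victim)
    if (!length(keep)) {
      # nothing survives elimination: the final model is intercept-only
      fit <- stats::glm(y ~ 1, family = stats::binomial())
      return(list(terms = character(),
                  summary = data.frame(term = character(), or = numeric(),
                                       ci_low = numeric(), ci_high = numeric(),
                                       p = numeric()),
                  removed = removed, fit = fit))
    }
  }
}
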