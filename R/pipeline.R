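#' Carrier-model association screen across the panel
#'
#' Stage-1 statistics for every panel SNP: minor-allele counts by group,
#' the chi-square/Fisher group comparison, and univariate logistic
#' regression of case status on carriage of the minor allele.  SNPs with
#' univariate p below `alpha` (strictly; default 0.1) are offered to a
#' multivariate logistic model with backward elimination at
#' `alpha_multi`, alongside any obliged covariates, which are never
#' removed.
#'
#' @param genotypes `genotype_matrix`.
#' @param cohort `cohort_table`.
#' @param alpha univariate screening threshold (default 0.1).
#' @param alpha_multi elimination threshold (default 0.05).
#' @param obliged_covariates cohort column names forced into the
#'   multivariate model (e.g. `culture_positive`, `prm_at_6m` for the
#'   12-month analysis).
#' @return list with `univariate` (one row per SNP: counts, OR, CI, p,
#'   candidate/retained flags, adjusted OR and p for retained SNPs) and
#'   `multivariate` (the [multivariate_backward()] result, or NULL when
#'   no candidate passes the screen).
#' @export
screen_snps <- function(genotypes, cohort, alpha = 0.1, alpha_multi = 0.05,
                        obliged_covariates = character()) {
  ord <- match(cohort$subject_id, genotypes$subject_ids)
  D <- genotypes$dosage[ord, , drop = FALSE]
  panel <- genotypes$panel
  uni <- lapply(seq_len(ncol(D)), function(j) {
    carrier <- carrier_indicator(D[, j])
    ac <- allele_counts(genotypes, cohort, panel$rsid[j])
    row <- data.frame(gene = panel$gene[j], rsid = panel$rsid[j],
                      allele = panel$minor_allele[j],
                      case_minor_n = ac$minor_count[ac$group == "case"],
                      case_minor_pct = ac$percent[ac$group == "case"],
                      control_minor_n = ac$minor_count[ac$group == "control"],
                      control_minor_pct = ac$percent[ac$group == "control"])
    ok <- !is.na(carrier)
    tab <- matrix(c(sum(cohort$status == 1 & carrier == 1, na.rm = TRUE),
                    sum(cohort$status == 1 & carrier == 0, na.rm = TRUE),
                    sum(cohort$status == 0 & carrier == 1, na.rm = TRUE),
                    sum(cohort$status == 0 & carrier == 0, na.rm = TRUE)),
                  2, 2, byrow = TRUE)
    gc <- tryCatch(group_compare_p(tab), error = function(e) NULL)
    ul <- tryCatch(univariate_logistic(cohort$status, carrier),
                   error = function(e) NULL)
    row$group_p <- gc$p_value %||% NA_real_
    row$group_test <- gc$test_used %||% NA_character_
    row$or <- ul$or %||% NA_real_
    row$ci_low <- if (is.null(ul)) NA_real_ else ul$ci95[1]
    row$ci_high <- if (is.null(ul)) NA_real_ else ul$ci95[2]
    row$p <- ul$p %||% NA_real_
    row$separation <- isTRUE(ul$separation)
    row
  })
  uni <- do.call(rbind, uni)
  uni$candidate <- !is.na(uni$p) & uni$p < alpha
  uni$retained_multivariate <- FALSE
  uni$or_adj <- NA_real_; uni$adj_low <- NA_real_; uni$adj_high <- NA_real_
  uni$p_adj <- NA_real_
  multi <- NULL
  cand <- uni$rsid[uni$candidate]
  if (length(cand)) {
    X <- as.data.frame(lapply(cand, function(rs)
      carrier_indicator(D[, match(rs, panel$rsid)])))
    names(X) <- cand
    for (cv in obliged_covariates) X[[cv]] <- as.numeric(cohort[[cv]])
    multi <- multivariate_backward(cohort$status, X,
                                   obliged = obliged_covariates,
                                   alpha = alpha_multi)
    hit <- match(multi$summary$term, uni$rsid)
    keep <- !is.na(hit)
    uni$retained_multivariate[hit[keep]] <- TRUE
    uni$or_adj[hit[keep]] <- multi$summary$or[keep]
    uni$adj_low[hit[keep]] <- multi$summary$ci_low[keep]
    uni$adj_high[hit[keep]] <- multi$summary$ci_high[keep]
    uni$p_adj[hit[keep]] <- multi$summary$p[keep]
  }
  list(univariate = uni, multivariate = multi)
}

#' Demographic/clinical summary of a cohort
#'
#' Per-group (case/control) means +/- SD for age and weight with a Welch
#' t-test (Mann-Whitney available), and counts (%) with the
#' chi-square/Fisher group comparison for binary rows.  With a single
#' group no p-values are computed.
#'
#' @param cohort `cohort_table`.
#' @param age_test `"welch"` (default) or `"wilcoxon"`.
#' @return data.frame, one row per characteristic.
#' @export
summarize_cohort <- function(cohort, age_test = c("welch", "wilcoxon")) {
  age_test <- match.arg(age_test)
  if (!nrow(cohort)) stopf("empty cohort")
  two_groups <- length(unique(cohort$status)) == 2
  case <- cohort[cohort$status == 1, ]
  ctrl <- cohort[cohort$status == 0, ]
  msd <- function(x) sprintf("%.1f \u00b1 %.1f", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  npct <- function(x) sprintf("%d (%.0f)", sum(x, na.rm = TRUE),
                              100 * mean(x, na.rm = TRUE))
  cont_row <- function(label, var) {
    p <- if (two_groups) {
      tryCatch(
        if (age_test == "welch") stats::t.test(case[[var]], ctrl[[var]])$p.value
        else stats::wilcox.test(case[[var]], ctrl[[var]], exact = FALSE)$p.value,
        error = function(e) NA_real_)
    } else NA_real_
    data.frame(variable = label, case = msd(case[[var]]), control = msd(ctrl[[var]]),
               p_value = p)
  }
  bin_row <- function(label, var) {
    if (!var %in% names(cohort) || all(is.na(cohort[[var]]))) return(NULL)
    p <- if (two_groups) {
      tab <- matrix(c(sum(case[[var]], na.rm = TRUE), sum(!case[[var]], na.rm = TRUE),
                      sum(ctrl[[var]], na.rm = TRUE), sum(!ctrl[[var]], na.rm = TRUE)),
                    2, 2, byrow = TRUE)
      tryCatch(group_compare_p(tab)$p_value, error = function(e) NA_real_)
    } else NA_real_
    data.frame(variable = label, case = npct(case[[var]]), control = npct(ctrl[[var]]),
               p_value = p)
  }
  out <- rbind(
    data.frame(variable = "n", case = as.character(nrow(case)),
               control = as.character(nrow(ctrl)), p_value = NA_real_),
    cont_row("Age (months)", "age_months"),
    bin_row("Female (%)", "female"),
    bin_row("Non-White race (%)", "non_white"),
    bin_row("Hispanic (%)", "hispanic"),
    cont_row("Weight (kg)", "weight_kg"),
    bin_row("Positive bacterial culture (%)", "culture_positive"),
    bin_row("PDAD (%)", "pdad"),
    bin_row("PRM at 6 months (%)", "prm_at_6m"))
  if (!two_groups) out$p_value <- NULL
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes cohort QC (allele counts, Hardy-Weinberg), the carrier-model
#' screen with multivariate backward elimination, and the 1-, 2- and
#' 3-SNP interaction sweeps, writing one TSV per report table, a JSON run
#' manifest and a log under `out_dir`.  Inputs come either from files
#' (`panel`, `genotypes`, `cohort` paths) or from a simulation spec.
#'
#' @param config list with either `sim_spec` (a [simulation_spec()]) or
#'   `paths = list(panel=, genotypes=, cohort=)`; optional `convention`,
#'   `screen_alpha` (0.1), `eliminate_alpha` (0.05), `report_threshold`
#'   (0.05), `fdr_q` (0.05), `fdr_family` ("per_order" or "global"),
#'   `obliged_covariates`, `orders` (default 1:3).
#' @param out_dir output directory (created if needed).
#' @return list with all computed tables (invisibly also written to
#'   disk) and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_log(clear = TRUE)
  cfg <- config
  cfg$convention <- cfg$convention %||% "paper_literal"
  cfg$screen_alpha <- cfg$screen_alpha %||% 0.1
  cfg$eliminate_alpha <- cfg$eliminate_alpha %||% 0.05
  cfg$report_threshold <- cfg$report_threshold %||% 0.05
  cfg$fdr_q <- cfg$fdr_q %||% 0.05
  cfg$fdr_family <- cfg$fdr_family %||% "per_order"
  cfg$orders <- cfg$orders %||% 1:3
  stage <- "input"
  manifest <- list(package_version = as.character(utils::packageVersion("prmepi")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config_hash = config_hash(cfg), completed = FALSE)
  out <- list()
  res <- tryCatch({
    if (!is.null(cfg$sim_spec)) {
      sim <- simulate_cohort(cfg$sim_spec)
      genotypes <- sim$genotypes; cohort <- sim$cohort
      manifest$seed <- cfg$sim_spec$seed
    } else {
      panel <- if (is.null(cfg$paths$panel)) load_default_panel()
               else read_panel(cfg$paths$panel)
      genotypes <- read_genotypes(cfg$paths$genotypes, panel)
      cohort <- read_cohort(cfg$paths$cohort, genotypes)
    }
    stage <- "summary"
    out$table1 <- summarize_cohort(cohort)
    write_tsv(out$table1, file.path(out_dir, "table1_summary.tsv"))
    stage <- "qc"
    out$qc <- qc_snps(genotypes, subset = match(cohort$subject_id, genotypes$subject_ids))
    write_tsv(out$qc, file.path(out_dir, "qc_snps.tsv"))
    stage <- "screen"
    scr <- screen_snps(genotypes, cohort, alpha = cfg$screen_alpha,
                       alpha_multi = cfg$eliminate_alpha,
                       obliged_covariates = cfg$obliged_covariates %||% character())
    out$screen <- scr$univariate
    out$multivariate <- scr$multivariate
    write_tsv(format_report(scr$univariate), file.path(out_dir, "screen_univariate.tsv"))
    stage <- "epistasis"
    manifest$n_tests <- list()
    for (k in cfg$orders) {
      stage <- sprintf("epistasis_k%d", k)
      mk <- run_model(k, genotypes, cohort, convention = cfg$convention,
                      report_threshold = cfg$report_threshold, fdr_q = cfg$fdr_q)
      out[[sprintf("model_k%d", k)]] <- mk
      manifest$n_tests[[sprintf("k%d", k)]] <- attr(mk, "n_tests")
    }
    if (cfg$fdr_family == "global") out <- refdr_global(out, cfg)
    for (k in cfg$orders)
      write_tsv(format_report(out[[sprintf("model_k%d", k)]]),
                file.path(out_dir, sprintf("model_k%d.tsv", k)))
    manifest$completed <- TRUE
    out
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    out
  })
  manifest$log <- get_log()
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(out_dir, "manifest.json"))
  writeLines(manifest$log %||% character(), file.path(out_dir, "log.txt"))
  res$manifest <- manifest
  invisible(res)
}

# One BH family across all model orders instead of one per order.
refdr_global <- function(out, cfg) {
  keys <- sprintf("model_k%d", cfg$orders)
  fams <- lapply(out[keys], attr, "all_tests")
  pool <- unlist(lapply(fams, `[[`, "p_adj"))
  fdr <- bh_fdr(pool, q = cfg$fdr_q)
  off <- 0
  for (i in seq_along(keys)) {
    fam <- fams[[i]]
    n <- nrow(fam)
    fam$fdr_q <- fdr$q_values[off + seq_len(n)]
    fam$significant_fdr <- fdr$significant[off + seq_len(n)]
    off <- off + n
    rec <- out[[keys[i]]]
    m <- match(interaction(rec$snp1, rec$effect_type, rec$p_adj),
               interaction(fam$snp1, fam$effect_type, fam$p_adj))
    rec$fdr_q <- fam$fdr_q[m]
    rec$significant_fdr <- fam$significant_fdr[m]
    attr(rec, "all_tests") <- fam
    out[[keys[i]]] <- rec
  }
  out
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

# Reports carry rounded display columns in the published style (OR to one
# decimal, p to two significant figures) next to full-precision values.
format_report <- function(df) {
  df <- as.data.frame(df)
  if ("or_mh" %in% names(df))
    df$or_display <- sprintf("%.1f (%.1f-%.1f)", df$or_mh, df$or_mh_low, df$or_mh_high)
  if ("or" %in% names(df) && "ci_low" %in% names(df))
    df$or_display <- sprintf("%.1f (%.1f-%.1f)", df$or, df$ci_low, df$ci_high)
  for (pc in intersect(c("p", "p_adj", "group_p"), names(df)))
    df[[paste0(pc, "_display")]] <- signif(df[[pc]], 2)
  df
}
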