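#!/usr/bin/env Rscript

# Step 2: cohort description, genotype QC and the carrier-model screen
# on the simulated cohorts from step 1.  Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(prmepi))

data_dir <- file.path("results", "data")
out <- file.path("results", "qc_screen")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
panel <- load_default_panel()

for (scenario in c("null", "planted")) {
  g <- read_genotypes(file.path(data_dir, sprintf("%s_genotypes.tsv", scenario)),
                      panel)
  co <- read_cohort(file.path(data_dir, sprintf("%s_cohort.tsv", scenario)))

  sm <- summarize_cohort(co)
  utils::write.table(sm, file.path(out, sprintf("%s_table1.tsv", scenario)),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  qc <- qc_snps(g)
  utils::write.table(qc, file.path(out, sprintf("%s_qc.tsv", scenario)),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scr <- screen_snps(g, co, obliged_covariates = "culture_positive")
  utils::write.table(scr$univariate,
                     file.path(out, sprintf("%s_screen.tsv", scenario)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scr$multivariate))
    utils::write.table(scr$multivariate$summary,
                       file.path(out, sprintf("%s_multivariate.tsv", scenario)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("QC and screening tables written to", out, "\n")
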