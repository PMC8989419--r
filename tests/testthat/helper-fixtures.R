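# Small deterministic fixtures built in code.

toy_panel <- function(n = 2) {
  p <- load_default_panel()
  p[seq_len(n), , drop = FALSE]
}

toy_genotypes <- function(dosage, panel = toy_panel(ncol(dosage))) {
  genotype_matrix(dosage, sprintf("S%02d", seq_len(nrow(dosage))), panel)
}

toy_cohort <- function(status, age = NULL, female = NULL, non_white = NULL,
                       weight = NULL, timepoint = "6m") {
  n <- length(status)
  cohort_table(data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    timepoint = rep(timepoint, length.out = n), status = status,
    age_months = age %||% rep(c(2, 6), length.out = n),
    female = female %||% rep(c(0, 1), length.out = n),
    non_white = non_white %||% rep(c(0, 0, 1), length.out = n),
    weight_kg = weight %||% rep(5, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_vcf_fixture <- function(path, alt_rs1130866 = "C") {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S01", "S02", "S03", sep = "\t"),
    paste("2", "85666", "rs1130866", "T", alt_rs1130866, ".", "PASS", ".",
          "GT", "0/1", "1/1", "0/0", sep = "\t"),
    paste("8", "22000", "rs4715", "C", "A", ".", "PASS", ".",
          "GT", "0/0", "./.", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}
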