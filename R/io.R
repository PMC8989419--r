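#' Construct a genotype matrix
#'
#' Dosage is the minor-allele count per subject and SNP: 0 (major-allele
#' homozygote), 1 (heterozygote), 2 (minor-allele homozygote) or `NA`.
#'
#' @param dosage integer matrix, subjects x SNPs; values in `{0,1,2,NA}`.
#' @param subject_ids character vector, one per row.
#' @param panel `snp_panel`, one row per column of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, subject_ids, panel) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(subject_ids))
    stopf("dosage has %d rows but %d subject ids", nrow(dosage), length(subject_ids))
  if (ncol(dosage) != nrow(panel))
    stopf("dosage has %d columns but panel has %d SNPs", ncol(dosage), nrow(panel))
  bad <- which(!is.na(dosage) & (dosage < 0L | dosage > 2L))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(dosage))
    stopf("dosage out of {0,1,2,NA} at row %d, column %d", i[1], i[2])
  }
  dimnames(dosage) <- list(subject_ids, panel$rsid)
  structure(list(subject_ids = as.character(subject_ids),
                 panel = panel, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect has a `subject_id` header column followed by rsID
#' columns, cells in `{0,1,2,NA}` (minor-allele dosage).  The VCF route
#' accepts biallelic records matched to the panel by ID; dosage is the
#' ALT-allele count and the record ALT must equal the panel minor allele.
#' rsIDs present in the file but absent from the panel are ignored with a
#' warning; panel SNPs absent from the file become all-missing columns
#' with a warning.
#'
#' @param path input file.
#' @param panel `snp_panel` the matrix is aligned to (column order).
#' @param format `"tsv"` or `"vcf"`.
#' @return A `genotype_matrix` aligned to `panel`.
#' @export
read_genotypes <- function(path, panel, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path, panel) else read_genotypes_vcf(path, panel)
}

read_genotypes_tsv <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  if (names(df)[1] != "subject_id") stopf("genotype TSV must start with a subject_id column")
  ids <- as.character(df$subject_id)
  snp_cols <- names(df)[-1]
  extra <- setdiff(snp_cols, panel$rsid)
  if (length(extra))
    log_note("read_genotypes: ignoring ", length(extra), " rsID(s) not in panel: ",
             paste(extra, collapse = ", "))
  dos <- matrix(NA_integer_, nrow(df), nrow(panel),
                dimnames = list(ids, panel$rsid))
  for (rs in intersect(panel$rsid, snp_cols)) {
    v <- df[[rs]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad))
      stopf("invalid dosage %s at row %d, column %s", v[bad[1]], bad[1], rs)
    dos[, rs] <- as.integer(v)
  }
  absent <- setdiff(panel$rsid, snp_cols)
  if (length(absent))
    log_note("read_genotypes: panel SNP(s) absent from file, set all-missing: ",
             paste(absent, collapse = ", "))
  genotype_matrix(dos, ids, panel)
}

read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix$ID %in% panel$rsid
  extra <- fix$ID[!keep]
  if (length(extra))
    log_note("read_genotypes: ignoring ", length(extra), " VCF record(s) not in panel: ",
             paste(extra, collapse = ", "))
  ids <- colnames(gt)
  dos <- matrix(NA_integer_, length(ids), nrow(panel),
                dimnames = list(ids, panel$rsid))
  for (i in which(keep)) {
    rs <- fix$ID[i]
    alt <- fix$ALT[i]
    if (grepl(",", alt)) stopf("non-biallelic VCF record for %s", rs)
    minor <- panel$minor_allele[match(rs, panel$rsid)]
    if (!identical(alt, minor))
      stopf("VCF ALT allele %s conflicts with panel minor allele %s for %s",
            alt, minor, rs)
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    dos[, rs] <- vapply(alleles, function(a) {
      if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  absent <- setdiff(panel$rsid, fix$ID)
  if (length(absent))
    log_note("read_genotypes: panel SNP(s) absent from VCF, set all-missing: ",
             paste(absent, collapse = ", "))
  genotype_matrix(dos, ids, panel)
}

#' Write a genotype matrix in the TSV dialect
#'
#' @param x `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(subject_id = x$subject_ids, x$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cohort_logical <- c("female", "non_white", "hispanic", "culture_positive",
                     "pdad", "prm_at_6m")

#' Construct/validate a cohort table
#'
#' One row per subject: case status (persistent respiratory morbidity at
#' the given timepoint) and covariates.  `status` is 1 for cases (PRM)
#' and 0 for controls.  Subjects older than 24 months at enrollment are
#' flagged with a warning (the study design enrolls 0-24 month olds) but
#' retained.
#'
#' @param df data frame with columns `subject_id`, `timepoint` ("6m" or
#'   "12m"), `status` (0/1), `age_months`, `female`, `non_white`,
#'   `weight_kg` and optionally `hispanic`, `culture_positive`, `pdad`,
#'   `prm_at_6m` (0/1 or logical, NA allowed).
#' @return The validated data frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("subject_id", "timepoint", "status", "age_months", "female",
            "non_white", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(df$timepoint %in% c("6m", "12m")))
    stopf("timepoint must be '6m' or '12m'")
  if (!all(df$status %in% c(0, 1))) stopf("status must be 0 (control) or 1 (case/PRM)")
  df$status <- as.integer(df$status)
  for (col in intersect(.cohort_logical, names(df))) {
    v <- df[[col]]
    if (!all(is.na(v) | v %in% c(0, 1, TRUE, FALSE)))
      stopf("column %s must be 0/1/NA", col)
    df[[col]] <- as.logical(v)
  }
  if (any(!is.na(df$age_months) & df$age_months < 0)) stopf("negative age_months")
  if (any(!is.na(df$weight_kg) & df$weight_kg <= 0)) stopf("non-positive weight_kg")
  over <- sum(df$age_months > 24, na.rm = TRUE)
  if (over) warning(sprintf("%d subject(s) older than 24 months at enrollment", over),
                    call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from TSV
#'
#' @param path TSV with the [cohort_table()] columns; booleans coded 0/1,
#'   missing as NA.
#' @param genotypes optional `genotype_matrix`; if given, subject ids are
#'   checked to match.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, genotypes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$subject_id <- as.character(df$subject_id)
  out <- cohort_table(df)
  if (!is.null(genotypes) && !setequal(out$subject_id, genotypes$subject_ids))
    stopf("cohort subject ids do not match the genotype matrix")
  out
}

#' Write a cohort table as TSV
#' @param x `cohort_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  df <- as.data.frame(x)
  for (col in intersect(.cohort_logical, names(df))) df[[col]] <- as.integer(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
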