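#' The default surfactant-protein SNP panel
#'
#' Fourteen single-nucleotide polymorphisms across the five surfactant
#' protein genes: five in *SFTPA1*, four in *SFTPA2*, one in *SFTPB*, two
#' in *SFTPC* and two in *SFTPD*.  Major/minor allele orientation follows
#' the dbSNP global population and is fixed by the panel definition, never
#' re-estimated from sample frequencies (a sample minor-allele frequency
#' may exceed 0.5, e.g. rs721917 at roughly 50%).  Alleles not fixed by
#' the published marker set are editable defaults: load a custom panel
#' with [read_panel()] to override them.
#'
#' @return A `data.frame` of class `snp_panel` with columns `rsid`,
#'   `gene`, `chromosome`, `locus_label`, `major_allele`, `minor_allele`.
#' @examples
#' p <- load_default_panel()
#' table(p$gene)
#' @export
load_default_panel <- function() {
  path <- system.file("extdata", "sp_panel.tsv", package = "prmepi")
  read_panel(path)
}

.sp_genes <- c("SFTPA1", "SFTPA2", "SFTPB", "SFTPC", "SFTPD")

#' Read a SNP panel definition
#'
#' @param path TSV file with columns `rsid`, `gene`, `major_allele`,
#'   `minor_allele` and optionally `chromosome`, `locus_label`.
#' @return A validated `snp_panel` data frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("rsid", "gene", "major_allele", "minor_allele")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("panel file lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(df$chromosome)) df$chromosome <- NA_character_
  if (is.null(df$locus_label)) df$locus_label <- NA_character_
  df <- df[c("rsid", "gene", "chromosome", "locus_label", "major_allele", "minor_allele")]
  validate_panel(df)
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Validate a SNP panel definition
#'
#' Checks rsid uniqueness, gene membership and allele coding; errors on
#' the first violation.
#'
#' @param df panel data frame.
#' @return The panel, invisibly.
#' @export
validate_panel <- function(df) {
  if (anyDuplicated(df$rsid)) stopf("duplicate rsid in panel: %s",
                                    paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
  bad <- setdiff(unique(df$gene), .sp_genes)
  if (length(bad)) stopf("unknown gene(s) in panel: %s", paste(bad, collapse = ", "))
  iupac <- c("A", "C", "G", "T")
  if (!all(df$major_allele %in% iupac) || !all(df$minor_allele %in% iupac))
    stopf("panel alleles must be one of A/C/G/T")
  eq <- df$major_allele == df$minor_allele
  if (any(eq)) stopf("major and minor allele identical for %s",
                     paste(df$rsid[eq], collapse = ", "))
  invisible(df)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d variants in %d genes\n",
              nrow(x), length(unique(x$gene))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
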