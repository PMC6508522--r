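#' Read a DEG comparison table (RNA-seq counts with qRT-PCR verdicts)
#'
#' Parses the tab-separated dialect used for cross-platform validation of
#' differential-expression calls: per-gene raw counts for the two
#' accessions, the reported RNA-seq fold (a number, "Absent in SH" or
#' "Absent in YK") and the qRT-PCR verdict (a linear fold, "Not detected in
#' SH"/"YK", "n.s." or "Not tested").  A copy of the published two-accession
#' DEG table ships with the package and is the default.
#'
#' @param path File path; defaults to the bundled table.
#' @return Tibble: gene_id, count_sh, count_yk, rnaseq_fold, rnaseq_absent,
#'   rnaseq_display, qpcr_fold, qpcr_absent, qpcr_ns, qpcr_tested.
#' @export
read_deg_table <- function(path = system.file("extdata", "table2_degs.tsv",
                                              package = "nightcontrast")) {
  x <- read_table_checked(path, "\t",
                          c("gene_id", "count_sh", "count_yk", "rnaseq", "qpcr"))
  absent_of <- function(s, prefix) {
    ifelse(grepl(paste0(prefix, " in SH"), s), "SH",
           ifelse(grepl(paste0(prefix, " in YK"), s), "YK", NA_character_))
  }
  tibble(
    gene_id = x$gene_id,
    count_sh = x$count_sh, count_yk = x$count_yk,
    rnaseq_fold = suppressWarnings(as.numeric(x$rnaseq)),
    rnaseq_absent = absent_of(x$rnaseq, "Absent"),
    rnaseq_display = x$rnaseq,
    qpcr_fold = suppressWarnings(as.numeric(x$qpcr)),
    qpcr_absent = absent_of(x$qpcr, "Not detected"),
    qpcr_ns = x$qpcr == "n.s.",
    qpcr_tested = x$qpcr != "Not tested"
  )
}
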