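vcf_filter_defs <- c(
  het_within_accession = "Heterozygous within at least one accession",
  not_biallelic = "More than two alleles at the site",
  low_alt_reads = "Alternative allele supported by fewer reads than the minimum",
  low_alt_fraction = "Alternative allele carried by too small a fraction of aligned reads",
  ref_discordant = "Accession-1 consensus differs from the reference base",
  snp_cluster = "Variant inside a dense cluster window"
)

#' Write SNP calls to a VCF v4.2 file
#'
#' Positions are written 1-based; the FILTER column is `PASS` or the
#' semicolon-joined failed-filter labels; INFO carries per-accession depths,
#' the alternative-allele fraction and the quality tier.  Every filter ID is
#' documented in the header.
#'
#' @param calls Annotated call tibble (see [call_snps()]).
#' @param path Output file path.
#' @param reference Optional named vector of reference sequences; when given,
#'   contig header lines are emitted.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nightcontrast",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">",
            names(vcf_filter_defs), vcf_filter_defs),
    "##INFO=<ID=DP1,Number=1,Type=Integer,Description=\"Read depth, accession 1\">",
    "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Read depth, accession 2\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele read fraction\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Quality tier (standard or high_quality)\">"
  )
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), nchar(reference)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- arrange(calls, .data$seq_id, .data$pos)
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\tDP1=%d;DP2=%d;AF=%.4f;TIER=%s",
            calls$seq_id, calls$pos, calls$ref_allele, calls$alt_allele,
            formatC(calls$quality, format = "fg"),
            ifelse(calls$filters == "", "PASS", calls$filters),
            calls$depth_a1, calls$depth_a2, calls$alt_fraction, calls$tier)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by [write_vcf()]
#'
#' @param path VCF file path.
#' @return Call tibble with seq_id, pos, ref_allele, alt_allele, quality,
#'   filters (empty string for PASS), pass, depth_a1, depth_a2, alt_fraction
#'   and tier.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    abort(paste0(path, ": not a VCF file"))
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(tibble(seq_id = character(), pos = integer(),
                  ref_allele = character(), alt_allele = character(),
                  quality = numeric(), filters = character(), pass = logical(),
                  depth_a1 = integer(), depth_a2 = integer(),
                  alt_fraction = numeric(), tier = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 8))
    abort(paste0(path, ": expected 8 tab-separated VCF columns"))
  f <- do.call(rbind, f)
  info <- f[, 8]
  grab <- function(key) sub(paste0(".*", key, "=([^;]+).*"), "\\1", info)
  tibble(
    seq_id = f[, 1], pos = as.integer(f[, 2]),
    ref_allele = f[, 4], alt_allele = f[, 5],
    quality = as.numeric(f[, 6]),
    filters = ifelse(f[, 7] == "PASS", "", f[, 7]),
    pass = f[, 7] == "PASS",
    depth_a1 = as.integer(grab("DP1")), depth_a2 = as.integer(grab("DP2")),
    alt_fraction = as.numeric(grab("AF")), tier = grab("TIER")
  )
}
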