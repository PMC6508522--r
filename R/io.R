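stop_at_line <- function(path, row, msg) {
  # +1 for the header line of every tabular dialect
  abort(sprintf("%s: line %d: %s", path, row + 1L, msg))
}

read_table_checked <- function(path, delim, required, check = NULL) {
  if (!file.exists(path)) abort(paste0(path, ": file not found"))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  if (!is.null(check)) check(x, path)
  x
}

#' Read / write the 9-column pileup dialect
#'
#' Tab-separated, header mandatory, UTF-8, 1-based positions.  Columns:
#' seq_id, pos, ref, A, C, G, T, depth, mapq.  Unknown extra columns are
#' preserved.  Malformed rows are rejected with the file name and line
#' number.
#'
#' @param path File path.
#' @return A pileup tibble.
#' @export
read_pileup <- function(path) {
  check <- function(x, path) {
    counts <- as.matrix(x[, c("A", "C", "G", "T")])
    bad <- which(rowSums(counts < 0 | counts != round(counts)) > 0)
    if (length(bad)) stop_at_line(path, bad[1], "negative or non-integer base count")
    bad <- which(!(x$ref %in% BASES))
    if (length(bad)) stop_at_line(path, bad[1], "ref must be one of A/C/G/T")
    bad <- which(x$pos < 1)
    if (length(bad)) stop_at_line(path, bad[1], "positions are 1-based (pos >= 1)")
    bad <- which(x$depth != rowSums(counts))
    if (length(bad)) stop_at_line(path, bad[1], "depth must equal A+C+G+T")
  }
  read_table_checked(path, "\t", c("seq_id", "pos", "ref", "A", "C", "G", "T",
                                   "depth", "mapq"), check)
}

#' @rdname read_pileup
#' @param pileup Pileup tibble.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path, progress = FALSE)
  invisible(path)
}

#' Read / write the two-accession gene count table
#'
#' Tab-separated with columns gene_id, count_sh, count_yk.
#'
#' @param path File path.
#' @return Count tibble.
#' @export
read_counts <- function(path) {
  check <- function(x, path) {
    for (col in c("count_sh", "count_yk")) {
      bad <- which(x[[col]] < 0 | x[[col]] != round(x[[col]]))
      if (length(bad))
        stop_at_line(path, bad[1],
                     paste0(col, " must be a non-negative integer"))
    }
    dup <- which(duplicated(x$gene_id))
    if (length(dup)) stop_at_line(path, dup[1], "duplicated gene_id")
  }
  read_table_checked(path, "\t", c("gene_id", "count_sh", "count_yk"), check)
}

#' @rdname read_counts
#' @param counts Count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read the long-format metabolite table
#'
#' Comma-separated with columns metabolite, class, experiment, genotype,
#' replicate, value.
#'
#' @param path File path.
#' @return Long metabolite tibble.
#' @export
read_metabolites <- function(path) {
  check <- function(x, path) {
    bad <- which(x$value < 0)
    if (length(bad)) stop_at_line(path, bad[1], "value must be >= 0")
    key <- paste(x$metabolite, x$experiment, x$genotype, x$replicate)
    dup <- which(duplicated(key))
    if (length(dup))
      stop_at_line(path, dup[1],
                   "duplicated (metabolite, experiment, genotype, replicate)")
  }
  read_table_checked(path, ",", c("metabolite", "class", "experiment",
                                  "genotype", "replicate", "value"), check)
}

#' Read qPCR CT tables
#'
#' `read_qpcr_dilutions()`: comma-separated dilution series with columns
#' primer, concentration, replicate, ct.  `read_qpcr_samples()`:
#' comma-separated sample measurements with columns gene_id, accession,
#' ct_target, ct_reference; missing CTs encode no amplification.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_qpcr_dilutions <- function(path) {
  check <- function(x, path) {
    bad <- which(x$concentration <= 0)
    if (length(bad)) stop_at_line(path, bad[1], "concentration must be > 0")
  }
  read_table_checked(path, ",", c("primer", "concentration", "replicate", "ct"),
                     check)
}

#' @rdname read_qpcr_dilutions
#' @export
read_qpcr_samples <- function(path) {
  read_table_checked(path, ",", c("gene_id", "accession", "ct_target",
                                  "ct_reference"))
}

#' Read / write reference transcripts as FASTA
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
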