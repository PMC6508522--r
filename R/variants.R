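#' Variant filter configuration
#'
#' Thresholds of the site-level filter cascade used to call fixed differences
#' between two inbred accessions.  Defaults follow the analysis contract:
#' mapping quality >= 15 and depth >= 3 for candidate detection; removal of
#' sites heterozygous within an accession, non-biallelic sites, variants with
#' fewer than 3 supporting reads or carried by < 10% of aligned reads, sites
#' where accession 1 disagrees with the reference, and any variant inside a
#' 100-bp window holding more than four passing variants.
#'
#' @param min_mapq Minimum representative mapping quality for a candidate.
#' @param min_depth Minimum per-accession read depth for a candidate.
#' @param min_alt_reads Minimum reads supporting the alternative allele.
#' @param min_alt_fraction Minimum fraction of aligned reads carrying the
#'   alternative allele.
#' @param monomorphic_max_minor_fraction A site counts as monomorphic within
#'   an accession when its minor-allele read fraction is at or below this
#'   value; the same cut defines which alleles count toward biallelism.
#' @param cluster_max_snps Maximum passing variants tolerated in one window;
#'   strictly more triggers the cluster flag.
#' @param cluster_window_bp Cluster window width in bp.
#' @param require_ref_concordance Flag candidates whose accession-1 consensus
#'   differs from the reference base.
#' @param alt_fraction_scope `"pooled"` evaluates the alternative-allele
#'   fraction over reads pooled across both accessions (plain reading of
#'   "aligned reads"); `"per_accession"` evaluates it within the
#'   alternative-carrying accession.
#' @param error_rate Per-read miscall rate of the symmetric binomial model
#'   behind the Phred-scaled site quality.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mapq = 15, min_depth = 3, min_alt_reads = 3,
                          min_alt_fraction = 0.10,
                          monomorphic_max_minor_fraction = 0.10,
                          cluster_max_snps = 4L, cluster_window_bp = 100L,
                          require_ref_concordance = TRUE,
                          alt_fraction_scope = c("pooled", "per_accession"),
                          error_rate = 1e-3) {
  stopifnot(min_mapq >= 0, min_depth >= 0, min_alt_reads >= 0,
            min_alt_fraction >= 0, monomorphic_max_minor_fraction >= 0,
            cluster_max_snps >= 0, cluster_window_bp >= 1)
  cfg <- list(min_mapq = min_mapq, min_depth = min_depth,
              min_alt_reads = min_alt_reads,
              min_alt_fraction = min_alt_fraction,
              monomorphic_max_minor_fraction = monomorphic_max_minor_fraction,
              cluster_max_snps = as.integer(cluster_max_snps),
              cluster_window_bp = as.integer(cluster_window_bp),
              require_ref_concordance = require_ref_concordance,
              alt_fraction_scope = match.arg(alt_fraction_scope),
              error_rate = error_rate)
  class(cfg) <- "filter_config"
  cfg
}

check_pileup_sorted <- function(p, label) {
  o <- order(p$seq_id, p$pos, method = "radix")
  if (!identical(o, seq_len(nrow(p))))
    abort(paste0(label, ": pileup must be sorted by (seq_id, pos)"))
  if (!all(p$ref %in% BASES))
    abort(paste0(label, ": reference base must be one of A/C/G/T"))
  invisible(p)
}

# Phred-scaled posterior against the no-difference hypothesis, capped at 999.
# Reads are modelled as independent miscalls at `error_rate`; the competing
# hypotheses are (same) both accessions homozygous for the accession-1
# consensus vs (diff) each accession homozygous for its own consensus.
snp_quality <- function(c1, c2, cons1, cons2, error_rate = 1e-3) {
  le <- log(error_rate / 3)
  lc <- log1p(-error_rate)
  n <- nrow(c1)
  i <- seq_len(n)
  d1 <- rowSums(c1); d2 <- rowSums(c2)
  ll <- function(cnt, d, g) cnt[cbind(i, g)] * lc + (d - cnt[cbind(i, g)]) * le
  l_same <- ll(c1, d1, cons1) + ll(c2, d2, cons1)
  l_diff <- ll(c1, d1, cons1) + ll(c2, d2, cons2)
  x <- l_diff - l_same                 # log BF for a real difference
  q <- 10 / log(10) * ifelse(x > 40, x, log1p(exp(pmax(x, -700))))
  pmin(round(q, 1), 999)
}

consensus_base <- function(m) max.col(m, ties.method = "first")

#' Call candidate accession-differentiating SNPs from paired pileups
#'
#' Joins the two accessions' pileups on (seq_id, pos) and emits a candidate
#' wherever the consensus bases differ, both depths reach `min_depth` and the
#' site's mapping quality reaches `min_mapq`.  Only substitutions are
#' representable in the pileup dialect, so indels never enter.  Each
#' candidate carries both accessions' full base counts (needed by
#' [apply_cascade()]), a Phred-scaled quality capped at 999 and the derived
#' `standard` / `high_quality` tier.
#'
#' @param pileup_sh,pileup_yk Pileup tibbles (see [simulate_pileups()] or
#'   [read_pileup()]) for accession 1 (reference-matching, "SH"-like) and
#'   accession 2 ("YK"-like), sorted by (seq_id, pos).
#' @param config A [filter_config()].
#' @return A tibble of candidate calls: seq_id, pos, ref_allele, alt_allele,
#'   depth_a1, depth_a2, alt_fraction, quality, tier, plus per-accession base
#'   counts (a1_A..a1_T, a2_A..a2_T) and consensus columns.
#' @export
call_candidate_snps <- function(pileup_sh, pileup_yk, config = filter_config()) {
  check_pileup_sorted(pileup_sh, "accession 1")
  check_pileup_sorted(pileup_yk, "accession 2")
  j <- inner_join(pileup_sh, pileup_yk, by = c("seq_id", "pos", "ref"),
                  suffix = c("_a1", "_a2"))
  c1 <- as.matrix(j[, c("A_a1", "C_a1", "G_a1", "T_a1")])
  c2 <- as.matrix(j[, c("A_a2", "C_a2", "G_a2", "T_a2")])
  d1 <- rowSums(c1); d2 <- rowSums(c2)
  cons1 <- consensus_base(c1)
  cons2 <- consensus_base(c2)
  mapq <- pmin(j$mapq_a1, j$mapq_a2)
  ref_int <- match(j$ref, BASES)

  keep <- cons1 != cons2 & d1 >= config$min_depth & d2 >= config$min_depth &
    mapq >= config$min_mapq
  j <- j[keep, ]; c1 <- c1[keep, , drop = FALSE]; c2 <- c2[keep, , drop = FALSE]
  cons1 <- cons1[keep]; cons2 <- cons2[keep]; ref_int <- ref_int[keep]
  d1 <- d1[keep]; d2 <- d2[keep]

  # the alternative allele is the non-reference member of the consensus pair,
  # preferring the accession-2 consensus when both are off-reference
  alt_int <- ifelse(cons2 != ref_int, cons2, cons1)
  i <- seq_len(nrow(j))
  alt_reads <- c1[cbind(i, alt_int)] + c2[cbind(i, alt_int)]
  alt_frac <- ifelse(d1 + d2 > 0, alt_reads / (d1 + d2), 0)
  qual <- snp_quality(c1, c2, cons1, cons2, config$error_rate)

  tibble(
    seq_id = j$seq_id, pos = j$pos,
    ref_allele = BASES[ref_int], alt_allele = BASES[alt_int],
    depth_a1 = as.integer(d1), depth_a2 = as.integer(d2),
    alt_fraction = alt_frac, quality = qual,
    tier = ifelse(qual >= 999, "high_quality", "standard"),
    cons_a1 = BASES[cons1], cons_a2 = BASES[cons2],
    a1_A = c1[, 1], a1_C = c1[, 2], a1_G = c1[, 3], a1_T = c1[, 4],
    a2_A = c2[, 1], a2_C = c2[, 2], a2_G = c2[, 3], a2_T = c2[, 4],
    filters = ""
  )
}

#' Annotate candidates with every failed cascade filter
#'
#' Evaluates the five site-level predicates on each candidate's own base
#' counts and appends the labels of every failed filter: `het_within_accession`
#' (in either accession, a second allele whose read fraction exceeds the
#' monomorphism cut with at least `min_alt_reads` supporting reads, so that
#' isolated miscalls cannot mimic heterozygosity), `not_biallelic` (more than two alleles once the reference, the
#' alternative and any substantially supported base are pooled),
#' `low_alt_reads`, `low_alt_fraction`, and `ref_discordant` (accession-1
#' consensus differs from the reference).  Annotation is total and depends
#' only on per-site data, so evaluation order cannot change the PASS set.
#'
#' @param candidates Output of [call_candidate_snps()].
#' @param config A [filter_config()].
#' @return The candidates with `filters` (semicolon-joined labels, empty for
#'   PASS) and logical `pass` columns.
#' @export
apply_cascade <- function(candidates, config = filter_config()) {
  if (nrow(candidates) == 0)
    return(mutate(candidates, pass = logical(0)))
  c1 <- as.matrix(candidates[, c("a1_A", "a1_C", "a1_G", "a1_T")])
  c2 <- as.matrix(candidates[, c("a2_A", "a2_C", "a2_G", "a2_T")])
  d1 <- rowSums(c1); d2 <- rowSums(c2)
  i <- seq_len(nrow(candidates))
  ref_int <- match(candidates$ref_allele, BASES)
  alt_int <- match(candidates$alt_allele, BASES)
  mono <- config$monomorphic_max_minor_fraction

  # heterozygosity evidence = the second allele's reads, which must both
  # exceed the monomorphism fraction and reach the minimum read support
  # (isolated miscalls at plausible error rates never fire the filter)
  second <- function(m) apply(m, 1, function(r) sort(r, decreasing = TRUE)[2])
  s1 <- second(c1); s2 <- second(c2)
  het <- (d1 > 0 & s1 / pmax(d1, 1L) > mono & s1 >= config$min_alt_reads) |
    (d2 > 0 & s2 / pmax(d2, 1L) > mono & s2 >= config$min_alt_reads)

  f1 <- c1 / pmax(d1, 1L)
  f2 <- c2 / pmax(d2, 1L)
  supported <- f1 > mono | f2 > mono
  supported[cbind(i, ref_int)] <- TRUE
  supported[cbind(i, alt_int)] <- TRUE
  not_biallelic <- rowSums(supported) > 2

  alt_reads <- c1[cbind(i, alt_int)] + c2[cbind(i, alt_int)]
  low_alt_reads <- alt_reads < config$min_alt_reads
  alt_frac <- if (config$alt_fraction_scope == "pooled") {
    ifelse(d1 + d2 > 0, alt_reads / (d1 + d2), 0)
  } else {
    carrier2 <- c2[cbind(i, alt_int)] >= c1[cbind(i, alt_int)]
    ifelse(carrier2, c2[cbind(i, alt_int)] / pmax(d2, 1L),
           c1[cbind(i, alt_int)] / pmax(d1, 1L))
  }
  low_alt_fraction <- alt_frac < config$min_alt_fraction

  cons1 <- consensus_base(c1)
  ref_discordant <- config$require_ref_concordance & cons1 != ref_int

  lab <- cbind(het_within_accession = het, not_biallelic = not_biallelic,
               low_alt_reads = low_alt_reads,
               low_alt_fraction = low_alt_fraction,
               ref_discordant = ref_discordant)
  new_filters <- apply(lab, 1, function(r) paste(colnames(lab)[r], collapse = ";"))
  mutate(candidates, filters = new_filters, pass = new_filters == "")
}

flag_windows <- function(pos, window, max_snps) {
  # pos sorted; flag every position inside some window of `window` bp holding
  # strictly more than `max_snps` positions
  n <- length(pos)
  flag <- logical(n)
  jmax <- findInterval(pos + window - 1L, pos)
  for (a in seq_len(n)) {
    b <- jmax[a]
    if (b - a + 1L > max_snps) flag[a:b] <- TRUE
  }
  flag
}

#' Flag variants falling in dense clusters
#'
#' Slides a `cluster_window_bp` window over the passing candidates of each
#' sequence and appends the `snp_cluster` label to every call that belongs to
#' any window holding strictly more than `cluster_max_snps` passing
#' candidates (misaligned reads around indel polymorphism produce such
#' clusters).  Non-passing calls are left untouched.
#'
#' @param calls Output of [apply_cascade()], position-sorted within seq_id.
#' @param config A [filter_config()].
#' @return The calls with updated `filters` / `pass` columns.
#' @export
cluster_filter <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  stopifnot(!is.null(calls$pass))
  flagged <- rep(FALSE, nrow(calls))
  idx_pass <- which(calls$pass)
  for (sid in unique(calls$seq_id[idx_pass])) {
    sel <- idx_pass[calls$seq_id[idx_pass] == sid]
    p <- calls$pos[sel]
    if (is.unsorted(p)) abort("cluster_filter: calls must be position-sorted within seq_id")
    flagged[sel] <- flag_windows(p, config$cluster_window_bp,
                                 config$cluster_max_snps)
  }
  calls |>
    mutate(
      filters = ifelse(flagged,
                       ifelse(.data$filters == "", "snp_cluster",
                              paste(.data$filters, "snp_cluster", sep = ";")),
                       .data$filters),
      pass = .data$filters == ""
    )
}

#' Full SNP calling pipeline on paired pileups
#'
#' Convenience wrapper: [call_candidate_snps()], then [apply_cascade()], then
#' [cluster_filter()].
#'
#' @inheritParams call_candidate_snps
#' @return Annotated call tibble; PASS rows have `filters == ""`.
#' @export
call_snps <- function(pileup_sh, pileup_yk, config = filter_config()) {
  call_candidate_snps(pileup_sh, pileup_yk, config) |>
    apply_cascade(config) |>
    cluster_filter(config)
}

#' Position and allele concordance between two call sets
#'
#' @param calls_a,calls_b Call tibbles with seq_id, pos, ref_allele,
#'   alt_allele (same reference naming).
#' @return One-row tibble: n_a, n_b, shared (positions in both), allele_match
#'   (shared positions with identical ref and alt), match_fraction
#'   (allele_match / shared), unique_a, unique_b.
#' @export
snp_concordance <- function(calls_a, calls_b) {
  key <- function(x) paste(x$seq_id, x$pos)
  ka <- key(calls_a); kb <- key(calls_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  match_n <- sum(calls_a$ref_allele[ia] == calls_b$ref_allele[ib] &
                 calls_a$alt_allele[ia] == calls_b$alt_allele[ib])
  n_shared <- length(shared)
  tibble(n_a = nrow(calls_a), n_b = nrow(calls_b),
         shared = n_shared, allele_match = match_n,
         match_fraction = if (n_shared) match_n / n_shared else NA_real_,
         unique_a = nrow(calls_a) - n_shared,
         unique_b = nrow(calls_b) - n_shared)
}
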