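# Builders for hand-constructed inputs.

# one-site pileup pair from named base-count vectors, e.g. c(A = 12)
site_pileups <- function(ref, a1, a2, pos = 100L, seq_id = "t1", mapq = 40L) {
  row <- function(counts) {
    full <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
    full[names(counts)] <- counts
    tibble::tibble(seq_id = seq_id, pos = as.integer(pos), ref = ref,
                   A = full[["A"]], C = full[["C"]], G = full[["G"]],
                   T = full[["T"]], depth = sum(full), mapq = mapq)
  }
  list(sh = row(a1), yk = row(a2))
}

# candidate row as apply_cascade() consumes it, without going through
# call_candidate_snps() (lets tests pose sites the caller would not emit)
make_candidate <- function(ref, alt, a1, a2, pos = 1L, seq_id = "t1") {
  full <- function(counts) {
    v <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
    v[names(counts)] <- counts
    v
  }
  c1 <- full(a1); c2 <- full(a2)
  tibble::tibble(
    seq_id = seq_id, pos = as.integer(pos),
    ref_allele = ref, alt_allele = alt,
    depth_a1 = sum(c1), depth_a2 = sum(c2),
    alt_fraction = (c1[[alt]] + c2[[alt]]) / max(1, sum(c1) + sum(c2)),
    quality = 0, tier = "standard",
    cons_a1 = names(which.max(c1)), cons_a2 = names(which.max(c2)),
    a1_A = c1[["A"]], a1_C = c1[["C"]], a1_G = c1[["G"]], a1_T = c1[["T"]],
    a2_A = c2[["A"]], a2_C = c2[["C"]], a2_G = c2[["G"]], a2_T = c2[["T"]],
    filters = ""
  )
}

# PASS-shaped call list at given positions on one sequence
calls_at <- function(pos, seq_id = "t1") {
  tibble::tibble(seq_id = seq_id, pos = as.integer(sort(pos)),
                 ref_allele = "A", alt_allele = "G",
                 depth_a1 = 10L, depth_a2 = 10L, alt_fraction = 0.5,
                 quality = 300, tier = "standard",
                 filters = "", pass = TRUE)
}

# long metabolite records from per-genotype replicate value vectors
metab_records <- function(sh1 = NULL, yk1 = NULL, sh2 = NULL, yk2 = NULL,
                          f1 = NULL, metabolite = "m1", class = "other") {
  piece <- function(vals, experiment, genotype) {
    if (is.null(vals)) return(NULL)
    tibble::tibble(metabolite = metabolite, class = class,
                   experiment = experiment, genotype = genotype,
                   replicate = seq_along(vals), value = vals)
  }
  dplyr::bind_rows(piece(sh1, 1L, "SH"), piece(yk1, 1L, "YK"),
                   piece(sh2, 2L, "SH"), piece(yk2, 2L, "YK"),
                   piece(f1, 2L, "F1"))
}

# calls + parent verdicts realizing a given 2x2 contingency table
# (rows: parents differ yes/no, cols: heterosis yes/no)
contingency_fixture <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  ids <- sprintf("m%03d", seq_len(n))
  diffp <- rep(c(TRUE, TRUE, FALSE, FALSE), c(n11, n10, n01, n00))
  het <- rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n10, n01, n00))
  calls <- tibble::tibble(
    metabolite = ids, mean_sh = 1, mean_yk = 2, f1_mean = 1.5,
    mid_parent = 1.5, below_mid_parent = FALSE,
    p_mid_parent = NA_real_, p_vs_sh = NA_real_, p_vs_yk = NA_real_,
    transgressive = ifelse(het, "low", "none"),
    p_transgressive = NA_real_, ratio = NA_real_,
    parent_detected = "both", class_call = NA_character_)
  parent_tests <- tibble::tibble(metabolite = ids, experiment = 2L,
                                 p_value = ifelse(diffp, 0.01, 0.5))
  list(calls = calls, parent_tests = parent_tests)
}
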