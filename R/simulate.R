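BASES <- c("A", "C", "G", "T")

# other_base_tab[b, ] = the three base codes != b
other_base_tab <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

# homozygous-consensus read counts with uniform miscalls at rate `err`
sim_base_counts <- function(depth, cons, err) {
  total <- length(depth)
  m <- matrix(0L, nrow = total, ncol = 4L)
  n_err <- rbinom(total, depth, err)
  e1 <- rbinom(total, n_err, 1 / 3)
  e2 <- rbinom(total, n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2
  m[cbind(seq_len(total), cons)] <- depth - n_err
  m[cbind(seq_len(total), other_base_tab[cbind(cons, 1L)])] <-
    m[cbind(seq_len(total), other_base_tab[cbind(cons, 1L)])] + e1
  m[cbind(seq_len(total), other_base_tab[cbind(cons, 2L)])] <-
    m[cbind(seq_len(total), other_base_tab[cbind(cons, 2L)])] + e2
  m[cbind(seq_len(total), other_base_tab[cbind(cons, 3L)])] <-
    m[cbind(seq_len(total), other_base_tab[cbind(cons, 3L)])] + e3
  m
}

as_pileup <- function(seq_id, pos, ref_int, counts, mapq) {
  tibble(
    seq_id = seq_id, pos = as.integer(pos), ref = BASES[ref_int],
    A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
    depth = as.integer(rowSums(counts)), mapq = as.integer(mapq)
  )
}

#' Simulate paired per-site pileups with planted SNPs and artifacts
#'
#' Generates a reference transcript set and one pileup table per accession.
#' Accession 1 matches the reference everywhere except at planted
#' reference-discordant artifacts; accession 2 carries the planted homozygous
#' SNPs.  Four artifact classes are planted at their configured rates:
#' heterozygous sites (roughly 50/50 read support within accession 2), thinly
#' supported variants (2 alternative reads at depth 4), reference-discordant
#' sites (both accessions non-reference and mutually different), and clusters
#' of 5-7 clean-looking substitutions confined to one 100-bp window.  True
#' SNPs within 100 bp of a planted cluster are suppressed so the two plantings
#' never overlap.
#'
#' @param config A [sim_config()].
#' @return A list with `reference` (named character vector of transcript
#'   sequences), `pileup_sh` and `pileup_yk` (tibbles in the 9-column pileup
#'   dialect: seq_id, pos, ref, A, C, G, T, depth, mapq; 1-based positions),
#'   and `truth` (list of tibbles `true_snps` and `artifact_sites`).
#' @export
simulate_pileups <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, "pileup"))

  n <- config$n_genes
  len_choices <- seq(config$gene_length_range[1], config$gene_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  gene_ids <- sprintf("gene%05d", seq_len(n))
  total <- sum(lens)
  offset <- c(0L, cumsum(lens))
  seq_id <- rep(gene_ids, lens)
  pos <- sequence(lens)
  ref <- sample.int(4L, total, replace = TRUE)

  # site classes, mutually exclusive by construction
  u <- runif(total)
  p1 <- config$snp_rate
  p2 <- p1 + config$het_artifact_rate
  p3 <- p2 + config$lowfrac_artifact_rate
  p4 <- p3 + config$refdisc_artifact_rate
  class <- rep("none", total)
  class[u < p4] <- "reference-discordant"
  class[u < p3] <- "low-fraction"
  class[u < p2] <- "heterozygous"
  class[u < p1] <- "snp"

  # planted SNP clusters, one 100-bp window per selected gene
  in_cluster_gene <- runif(n) < config$cluster_artifact_rate & lens >= 150L
  for (g in which(in_cluster_gene)) {
    ws <- sample.int(lens[g] - 99L, 1L)
    k <- sample(5:7, 1L)
    offs <- sample.int(100L, k) - 1L
    idx <- offset[g] + ws + offs
    guard <- offset[g] + max(1L, ws - 100L):min(lens[g], ws + 199L)
    class[guard] <- "none"            # keep clusters clear of other plantings
    class[idx] <- "cluster"
  }

  # alternative alleles (always != ref); reference-discordant sites get two
  # distinct non-reference bases, one per accession
  needs_alt <- class != "none"
  alt <- ref
  pick1 <- sample.int(3L, total, replace = TRUE)
  alt[needs_alt] <- other_base_tab[cbind(ref, pick1)][needs_alt]
  is_rd <- class == "reference-discordant"
  pick2 <- sample.int(2L, total, replace = TRUE)
  pick2 <- pick2 + (pick2 >= pick1)   # column index among 1:3, != pick1
  alt2 <- other_base_tab[cbind(ref, pick2)]

  d1 <- rpois(total, config$depth_mean)
  d2 <- rpois(total, config$depth_mean)

  cons1 <- ref
  cons1[is_rd] <- alt[is_rd]          # accession-1 consensus off-reference
  cons2 <- ref
  cons2[class %in% c("snp", "cluster")] <- alt[class %in% c("snp", "cluster")]
  cons2[is_rd] <- alt2[is_rd]

  m1 <- sim_base_counts(d1, cons1, config$seq_error_rate)
  m2 <- sim_base_counts(d2, cons2, config$seq_error_rate)

  # heterozygous artifact: ~50/50 ref/alt mixture within accession 2
  het <- which(class == "heterozygous")
  if (length(het)) {
    alt_n <- rbinom(length(het), d2[het], 0.5)
    m2[het, ] <- 0L
    m2[cbind(het, alt[het])] <- alt_n
    m2[cbind(het, ref[het])] <- d2[het] - alt_n
    d2[het] <- rowSums(m2[het, , drop = FALSE])
  }

  # low-fraction artifact: alternative consensus carried by only 2 of 4 reads
  lf <- which(class == "low-fraction")
  if (length(lf)) {
    other <- other_base_tab[cbind(ref[lf], 1L)]
    other[other == alt[lf]] <- other_base_tab[cbind(ref[lf], 2L)][other == alt[lf]]
    m2[lf, ] <- 0L
    m2[cbind(lf, alt[lf])] <- 2L
    m2[cbind(lf, ref[lf])] <- 1L
    m2[cbind(lf, other)] <- m2[cbind(lf, other)] + 1L
    d2[lf] <- 4L
  }

  reference <- vapply(split(BASES[ref], rep(seq_len(n), lens)),
                      paste, collapse = "", FUN.VALUE = character(1))
  names(reference) <- gene_ids

  truth <- list(
    true_snps = tibble(seq_id = seq_id[class == "snp"],
                       pos = as.integer(pos[class == "snp"]),
                       ref = BASES[ref[class == "snp"]],
                       alt = BASES[alt[class == "snp"]]),
    artifact_sites = tibble(seq_id = seq_id[class != "none" & class != "snp"],
                            pos = as.integer(pos[class != "none" & class != "snp"]),
                            class = class[class != "none" & class != "snp"])
  )

  list(reference = reference,
       pileup_sh = as_pileup(seq_id, pos, ref, m1, 40L),
       pileup_yk = as_pileup(seq_id, pos, ref, m2, 40L),
       truth = truth)
}

#' Simulate a two-accession gene count table with planted PAV and fold changes
#'
#' Draws per-gene baseline means from a lognormal scaled to the configured
#' library size, plants structural zeros for presence-absence genes (half in
#' each accession) and symmetric log2 fold changes for a small set of
#' differentially expressed genes, then samples negative-binomial counts.
#' Planted folds are restricted to genes whose baseline mean exceeds
#' `de_min_mean` so the planted signal is observable at the simulated depth.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble: gene_id, count_sh, count_yk) and
#'   `truth` (tibble: gene_id, base_mean, true_pav, is_de, true_log2_fold).
#' @export
simulate_counts <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, "counts"))

  n <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  base <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  base <- base * (config$total_reads / 2) / sum(base)

  pav <- runif(n) < config$pav_fraction
  side <- ifelse(runif(n) < 0.5, "sh_only", "yk_only")
  side[!pav] <- "both"

  eligible <- !pav & base >= config$de_min_mean
  is_de <- eligible & runif(n) < config$de_fraction
  lfc <- rep(0, n)
  lfc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
    runif(sum(is_de), config$fold_range[1], config$fold_range[2])

  mu_sh <- base * 2^(-lfc / 2)
  mu_yk <- base * 2^(lfc / 2)
  mu_yk[side == "sh_only"] <- 0
  mu_sh[side == "yk_only"] <- 0

  size <- 1 / config$nb_dispersion
  counts <- tibble(
    gene_id = gene_ids,
    count_sh = rnbinom(n, mu = mu_sh, size = size),
    count_yk = rnbinom(n, mu = mu_yk, size = size)
  )
  truth <- tibble(gene_id = gene_ids, base_mean = base, true_pav = side,
                  is_de = is_de,
                  true_log2_fold = ifelse(is_de, lfc, NA_real_))
  list(counts = counts, truth = truth)
}

#' Simulate a two-experiment metabolite panel with planted heterosis modes
#'
#' Each metabolite is assigned a heterosis mode from `heterosis_mix`:
#' additive (F1 mean at the mid-parent), dominant (F1 mean at one parent,
#' chosen at random), or transgressive (F1 mean beyond the extreme parent by
#' `transgressive_margin`).  Additive and dominant metabolites get
#' well-separated parental means (|log2 YK/SH| drawn from U(1.5, 2)) so the
#' planted modes are identifiable; additive metabolites keep equal parents
#' with probability 0.35, and transgressive metabolites keep equal parents
#' with probability 0.75, reproducing the association between transgression
#' and parentally equivalent metabolites.  Replicate values are lognormal
#' with coefficient of variation `cv_metab`; experiment 2 applies a
#' per-metabolite multiplicative environment shift shared by all genotypes.
#' A small fraction of metabolites is undetected (all-zero) in one parent.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (long tibble: metabolite, class, experiment,
#'   genotype, replicate, value) and `truth` (tibble: metabolite, class,
#'   mode, mean_sh, mean_yk, f1_mean, parent_detected).
#' @export
simulate_metabolome <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, "metabolome"))

  m <- config$n_metabolites
  ids <- sprintf("metab%03d", seq_len(m))
  class <- sample(c("carbohydrate", "fatty_acid", "amino_acid", "other"),
                  m, replace = TRUE, prob = c(0.35, 0.20, 0.15, 0.30))
  mode <- sample(names(config$heterosis_mix), m, replace = TRUE,
                 prob = config$heterosis_mix)
  base <- rlnorm(m, meanlog = log(500), sdlog = 1.5)

  trans <- mode %in% c("transgressive_up", "transgressive_down")
  parents_differ <- mode == "dominant" |
    (mode == "additive" & runif(m) < 0.65) |
    (trans & runif(m) < 0.25)
  lr <- ifelse(parents_differ,
               runif(m, 1.5, 2) * sample(c(-1, 1), m, replace = TRUE), 0)
  mean_sh <- base * 2^(-lr / 2)
  mean_yk <- base * 2^(lr / 2)

  sp <- runif(m) < config$single_parent_fraction
  absent <- sample(c("SH", "YK"), m, replace = TRUE)
  mean_sh[sp & absent == "SH"] <- 0
  mean_yk[sp & absent == "YK"] <- 0

  mid <- (mean_sh + mean_yk) / 2
  hi <- pmax(mean_sh, mean_yk)
  lo <- pmin(mean_sh, mean_yk)
  f1 <- mid
  dom <- mode == "dominant"
  f1[dom] <- ifelse(runif(sum(dom)) < 0.5, mean_sh[dom], mean_yk[dom])
  f1[mode == "transgressive_up"] <-
    hi[mode == "transgressive_up"] * (1 + config$transgressive_margin)
  f1[mode == "transgressive_down"] <-
    lo[mode == "transgressive_down"] / (1 + config$transgressive_margin)
  # undetected-in-one-parent metabolites: F1 follows the detected parent
  f1[sp] <- hi[sp]

  shift <- exp(rnorm(m, 0, config$experiment_shift_sd))
  sdlog <- sqrt(log(1 + config$cv_metab^2))

  grid <- bind_rows(
    tidyr::expand_grid(metabolite = ids, experiment = 1L,
                       genotype = c("SH", "YK"),
                       replicate = seq_len(config$metab_n1)),
    tidyr::expand_grid(metabolite = ids, experiment = 2L,
                       genotype = c("SH", "YK", "F1"),
                       replicate = seq_len(config$metab_n2))
  )
  idx <- match(grid$metabolite, ids)
  mu <- ifelse(grid$genotype == "SH", mean_sh[idx],
               ifelse(grid$genotype == "YK", mean_yk[idx], f1[idx]))
  mu <- mu * ifelse(grid$experiment == 2L, shift[idx], 1)
  value <- numeric(nrow(grid))
  posv <- mu > 0
  value[posv] <- rlnorm(sum(posv), meanlog = log(mu[posv]) - sdlog^2 / 2,
                        sdlog = sdlog)
  records <- grid |>
    mutate(class = class[idx], value = value) |>
    select("metabolite", "class", "experiment", "genotype", "replicate", "value") |>
    arrange(.data$metabolite, .data$experiment, .data$genotype, .data$replicate)

  truth <- tibble(metabolite = ids, class = class, mode = mode,
                  mean_sh = mean_sh, mean_yk = mean_yk, f1_mean = f1,
                  parent_detected = ifelse(sp, "one", "both"))
  list(records = records, truth = truth)
}

#' Simulate qPCR dilution-series and sample CT tables
#'
#' Dilution series: five relative concentrations in fivefold steps with
#' `qpcr_reps` technical replicates, CT = intercept + slope * log10(conc) +
#' Normal(0, qpcr_sd) per primer.  The sample table carries per-accession
#' target and reference-gene CTs for `n_qpcr_genes` genes with planted
#' log2(YK/SH) expression ratios, back-computed through the true efficiency.
#'
#' @param config A [sim_config()].
#' @return A list with `dilutions` (tibble: primer, concentration, replicate,
#'   ct), `samples` (tibble: gene_id, accession, ct_target, ct_reference) and
#'   `truth` (tibble: gene_id, true_log2_fold; plus attributes slope and
#'   efficiency via columns true_slope, true_efficiency).
#' @export
simulate_qpcr <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, "qpcr"))

  genes <- sprintf("target%02d", seq_len(config$n_qpcr_genes))
  primers <- c(genes, "reference")
  conc <- 5^-(0:4)
  dil <- tidyr::expand_grid(primer = primers, concentration = conc,
                            replicate = seq_len(config$qpcr_reps))
  prim_off <- setNames(runif(length(primers), -2, 2), primers)
  dil$ct <- config$qpcr_intercept + prim_off[dil$primer] +
    config$qpcr_slope * log10(dil$concentration) +
    rnorm(nrow(dil), 0, config$qpcr_sd)

  eff <- 10^(-1 / config$qpcr_slope) - 1
  true_lfc <- runif(config$n_qpcr_genes, -6, 6)
  ct_ref <- config$qpcr_intercept + rnorm(2 * config$n_qpcr_genes, 0, config$qpcr_sd)
  samples <- tidyr::expand_grid(gene_id = genes, accession = c("SH", "YK"))
  base_rel <- runif(config$n_qpcr_genes, 0.1, 4)
  rel <- ifelse(samples$accession == "SH",
                base_rel[match(samples$gene_id, genes)],
                base_rel[match(samples$gene_id, genes)] *
                  2^true_lfc[match(samples$gene_id, genes)])
  samples$ct_reference <- ct_ref
  samples$ct_target <- samples$ct_reference - log(rel) / log(1 + eff) +
    rnorm(nrow(samples), 0, config$qpcr_sd)

  truth <- tibble(gene_id = genes, true_log2_fold = true_lfc,
                  true_slope = config$qpcr_slope, true_efficiency = eff)
  list(dilutions = dil, samples = samples, truth = truth)
}
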