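#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator into one validated
#' object.  The defaults encode the study conditions the generator emulates:
#' two substantially inbred accessions ("SH"-like and "YK"-like) diverging at
#' about one SNP per 10 kb of transcribed sequence, pyrosequencing-era depth
#' and error rates, an expression table with 18.5% presence-absence genes and
#' rare large-fold differentially expressed genes at roughly one million total
#' reads, a metabolite panel measured in two experiments (n = 4 and n = 3
#' replicates per genotype) with additive, dominant and transgressive F1
#' modes, and a five-point fivefold qPCR dilution series.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.  Each output file draws from its own derived stream so files can
#'   be regenerated independently.
#' @param n_genes Number of reference transcripts / count-table genes.
#' @param gene_length_range Length interval (bp) for simulated transcripts.
#' @param snp_rate Per-bp probability that accession 2 carries a fixed
#'   homozygous substitution (default 1e-4, i.e. 1 SNP / 10 kb).
#' @param het_artifact_rate Fraction of sites planted as artifactually
#'   heterozygous within accession 2 (misalignment-style artifact).
#' @param lowfrac_artifact_rate Fraction of sites planted as thinly supported
#'   apparent variants (2 alternative reads at depth 4).
#' @param refdisc_artifact_rate Fraction of sites where accession 1 disagrees
#'   with the reference (both accessions non-reference, mutually different).
#' @param cluster_artifact_rate Fraction of genes given a planted cluster of
#'   >= 5 clean-looking substitutions inside one 100-bp window.
#' @param seq_error_rate Per-read uniform base miscall rate (default 0.005).
#' @param depth_mean Mean per-site read depth (Poisson), default 20.
#' @param total_reads Approximate total reads across both count columns.
#' @param pav_fraction Fraction of genes expressed in only one accession
#'   (default 0.185), split evenly between the accessions.
#' @param de_fraction Fraction of genes given a planted log2 fold change.
#' @param fold_range Absolute log2 fold interval for planted DE genes; the
#'   sign is drawn at random.
#' @param de_min_mean Minimum baseline mean for genes eligible to carry a
#'   planted fold (large folds on near-zero genes are unobservable at this
#'   depth, and the emulated candidates are well-covered).
#' @param nb_dispersion Negative-binomial dispersion of counts around the
#'   per-gene means.
#' @param n_metabolites Size of the metabolite panel (default 144).
#' @param metab_n1,metab_n2 Replicates per genotype in experiments 1 and 2
#'   (defaults 4 and 3).
#' @param heterosis_mix Named proportions (summing to 1) of additive,
#'   dominant, transgressive-up and transgressive-down metabolites.
#' @param transgressive_margin Fractional excursion of transgressive F1 means
#'   beyond the extreme parent (0.5 = 50% beyond).
#' @param cv_metab Replicate coefficient of variation of metabolite values.
#' @param experiment_shift_sd Standard deviation (log scale) of the
#'   per-metabolite multiplicative shift between the two experiments.
#' @param single_parent_fraction Fraction of metabolites undetected (all-zero)
#'   in one parent.
#' @param qpcr_slope True dilution-series slope (CT per log10 concentration).
#' @param qpcr_intercept True CT at relative concentration 1.
#' @param qpcr_sd CT measurement noise standard deviation.
#' @param qpcr_reps Technical replicates per dilution point.
#' @param n_qpcr_genes Number of target genes in the simulated sample CT table.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       gene_length_range = c(300L, 1500L),
                       snp_rate = 1e-4,
                       het_artifact_rate = 1e-4,
                       lowfrac_artifact_rate = 5e-5,
                       refdisc_artifact_rate = 5e-5,
                       cluster_artifact_rate = 0.05,
                       seq_error_rate = 0.005,
                       depth_mean = 20,
                       total_reads = 1e6,
                       pav_fraction = 0.185,
                       de_fraction = 31 / 18000,
                       fold_range = c(2, 8),
                       de_min_mean = 20,
                       nb_dispersion = 0.02,
                       n_metabolites = 144L,
                       metab_n1 = 4L,
                       metab_n2 = 3L,
                       heterosis_mix = c(additive = 0.50, dominant = 0.34,
                                         transgressive_up = 0.01,
                                         transgressive_down = 0.15),
                       transgressive_margin = 0.5,
                       cv_metab = 0.10,
                       experiment_shift_sd = 0.3,
                       single_parent_fraction = 4 / 144,
                       qpcr_slope = -3.3219,
                       qpcr_intercept = 20,
                       qpcr_sd = 0.2,
                       qpcr_reps = 3L,
                       n_qpcr_genes = 5L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    snp_rate = snp_rate, het_artifact_rate = het_artifact_rate,
    lowfrac_artifact_rate = lowfrac_artifact_rate,
    refdisc_artifact_rate = refdisc_artifact_rate,
    cluster_artifact_rate = cluster_artifact_rate,
    seq_error_rate = seq_error_rate, depth_mean = depth_mean,
    total_reads = total_reads, pav_fraction = pav_fraction,
    de_fraction = de_fraction, fold_range = fold_range,
    de_min_mean = de_min_mean, nb_dispersion = nb_dispersion,
    n_metabolites = as.integer(n_metabolites),
    metab_n1 = as.integer(metab_n1), metab_n2 = as.integer(metab_n2),
    heterosis_mix = heterosis_mix,
    transgressive_margin = transgressive_margin,
    cv_metab = cv_metab, experiment_shift_sd = experiment_shift_sd,
    single_parent_fraction = single_parent_fraction,
    qpcr_slope = qpcr_slope, qpcr_intercept = qpcr_intercept,
    qpcr_sd = qpcr_sd, qpcr_reps = as.integer(qpcr_reps),
    n_qpcr_genes = as.integer(n_qpcr_genes)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) abort("sim_config: n_genes must be >= 1")
  if (cfg$depth_mean <= 0) abort("sim_config: depth_mean must be > 0")
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1] < 100L ||
      diff(cfg$gene_length_range) < 0)
    abort("sim_config: gene_length_range must be an increasing bp interval >= 100")
  rates <- c(snp_rate = cfg$snp_rate, het_artifact_rate = cfg$het_artifact_rate,
             lowfrac_artifact_rate = cfg$lowfrac_artifact_rate,
             refdisc_artifact_rate = cfg$refdisc_artifact_rate,
             cluster_artifact_rate = cfg$cluster_artifact_rate,
             seq_error_rate = cfg$seq_error_rate,
             pav_fraction = cfg$pav_fraction, de_fraction = cfg$de_fraction,
             single_parent_fraction = cfg$single_parent_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    abort(paste0("sim_config: rates/fractions must lie in [0,1]: ",
                 paste(names(rates)[bad], collapse = ", ")))
  if (abs(sum(cfg$heterosis_mix) - 1) > 1e-8)
    abort("sim_config: heterosis_mix must sum to 1")
  need <- c("additive", "dominant", "transgressive_up", "transgressive_down")
  if (!all(need %in% names(cfg$heterosis_mix)))
    abort("sim_config: heterosis_mix must name additive, dominant, transgressive_up, transgressive_down")
  if (cfg$metab_n1 < 2L || cfg$metab_n2 < 2L)
    abort("sim_config: metabolite experiments need >= 2 replicates")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "| genes", x$n_genes,
      "| snp_rate", x$snp_rate, "| pav", x$pav_fraction,
      "| metabolites", x$n_metabolites, "\n")
  invisible(x)
}
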