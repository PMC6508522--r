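#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages of the comparative analysis in order — simulate,
#' SNP calling (`snp`), differential expression and presence-absence (`de`),
#' qPCR quantification (`qpcr`), metabolite statistics (`metab`) and
#' category enrichment (`enrich`) — writing every intermediate table to
#' `outdir` along with a provenance manifest (seed, package version,
#' configuration, per-stage row counts and output checksums).  Stages can be
#' toggled; a stage failure halts the run naming the stage and cause.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "snp", "de", "qpcr", "metab", "enrich")`.
#' @param filter_cfg A [filter_config()] for the SNP stage.
#' @param fdr FDR threshold for the DE stage.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "snp", "de", "qpcr",
                                    "metab", "enrich"),
                         filter_cfg = filter_config(), fdr = 0.2) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "nightcontrast",
                   version = as.character(utils::packageVersion("nightcontrast")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = list())
  note <- function(stage, rows, files) {
    manifest$stages[[stage]] <<- list(rows = rows, files = as.list(files))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) {
      message("pipeline: skipping stage ", stage)
      return(invisible(NULL))
    }
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  p <- function(f) file.path(outdir, f)

  run_stage("simulate", function() {
    pl <- simulate_pileups(config)
    write_fasta(pl$reference, p("reference.fasta"))
    write_pileup(pl$pileup_sh, p("pileup_sh.tsv"))
    write_pileup(pl$pileup_yk, p("pileup_yk.tsv"))
    readr::write_tsv(pl$truth$true_snps, p("truth_snps.tsv"), progress = FALSE)
    readr::write_tsv(pl$truth$artifact_sites, p("truth_artifacts.tsv"),
                     progress = FALSE)
    cn <- simulate_counts(config)
    write_counts(cn$counts, p("counts.tsv"))
    readr::write_tsv(cn$truth, p("truth_counts.tsv"), progress = FALSE)
    mb <- simulate_metabolome(config)
    readr::write_csv(mb$records, p("metabolites.csv"), progress = FALSE)
    readr::write_csv(mb$truth, p("truth_metabolome.csv"), progress = FALSE)
    qp <- simulate_qpcr(config)
    readr::write_csv(qp$dilutions, p("qpcr_dilutions.csv"), progress = FALSE)
    readr::write_csv(qp$samples, p("qpcr_samples.csv"), progress = FALSE)
    note("simulate", nrow(pl$pileup_sh),
         c("reference.fasta", "pileup_sh.tsv", "pileup_yk.tsv", "counts.tsv",
           "metabolites.csv", "qpcr_dilutions.csv", "qpcr_samples.csv"))
  })

  run_stage("snp", function() {
    calls <- call_snps(read_pileup(p("pileup_sh.tsv")),
                       read_pileup(p("pileup_yk.tsv")), filter_cfg)
    ref <- if (file.exists(p("reference.fasta"))) read_fasta(p("reference.fasta"))
    write_vcf(calls, p("snps.vcf"), reference = ref)
    note("snp", nrow(calls), "snps.vcf")
  })

  run_stage("de", function() {
    counts <- read_counts(p("counts.tsv"))
    de <- de_test(counts, fdr = fdr)
    readr::write_tsv(de, p("de_results.tsv"), progress = FALSE)
    readr::write_tsv(pav_summary(counts), p("pav_summary.tsv"), progress = FALSE)
    note("de", nrow(de), c("de_results.tsv", "pav_summary.tsv"))
  })

  run_stage("qpcr", function() {
    eff <- fit_efficiencies(read_qpcr_dilutions(p("qpcr_dilutions.csv")))
    readr::write_tsv(eff, p("qpcr_efficiency.tsv"), progress = FALSE)
    samples <- read_qpcr_samples(p("qpcr_samples.csv"))
    e_ref <- eff$efficiency[eff$primer == "reference"]
    e_use <- if (length(e_ref)) mean(eff$efficiency) else 1
    rel <- samples |>
      mutate(relative_expression = relative_expression(
        .data$ct_target, .data$ct_reference, e_use))
    readr::write_tsv(rel, p("qpcr_expression.tsv"), progress = FALSE)
    note("qpcr", nrow(rel), c("qpcr_efficiency.tsv", "qpcr_expression.tsv"))
  })

  run_stage("metab", function() {
    records <- read_metabolites(p("metabolites.csv"))
    tab <- metab_table(records)
    readr::write_tsv(tab, p("metabolite_tests.tsv"), progress = FALSE)
    calls <- heterosis_calls(records)
    readr::write_tsv(calls, p("heterosis.tsv"), progress = FALSE)
    summary <- list(
      starch_proxy = tryCatch(as.list(starch_proxy(records)),
                              error = function(e) NULL),
      mid_parent = as.list(mid_parent_fraction(calls)[1, ]),
      direction_binomial = as.list(direction_binomial(calls)),
      contingency = tidy(heterosis_contingency(
        calls, metab_ttest(records, experiments = 2L))) |> as.list()
    )
    jsonlite::write_json(summary, p("metabolite_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("metab", nrow(calls),
         c("metabolite_tests.tsv", "heterosis.tsv", "metabolite_summary.json"))
  })

  run_stage("enrich", function() {
    records <- read_metabolites(p("metabolites.csv"))
    tt <- metab_ttest(records, experiments = 2L)
    folds <- tibble(item_id = tt$metabolite,
                    log2_fold = log2(tt$mean_yk / tt$mean_sh))
    map <- distinct(records[, c("metabolite", "class")]) |>
      rename(item_id = "metabolite", category = "class")
    res <- enrich_categories(folds, map)
    readr::write_tsv(res, p("enrichment.tsv"), progress = FALSE)
    note("enrich", nrow(res), "enrichment.tsv")
  })

  all_files <- unlist(lapply(manifest$stages, function(s) unlist(s$files)))
  sums <- tools::md5sum(file.path(outdir, unique(all_files)))
  manifest$checksums <- as.list(setNames(unname(sums), unique(all_files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
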