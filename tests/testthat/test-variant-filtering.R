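test_that("candidates appear exactly where consensus bases differ", {
  s <- site_pileups("A", c(A = 12L), c(G = 9L))
  cand <- call_candidate_snps(s$sh, s$yk)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$ref_allele, "A")
  expect_equal(cand$alt_allele, "G")
  expect_equal(c(cand$depth_a1, cand$depth_a2), c(12L, 9L))

  mono <- site_pileups("A", c(A = 12L), c(A = 10L))
  expect_equal(nrow(call_candidate_snps(mono$sh, mono$yk)), 0)

  # depth and mapping-quality gates
  thin <- site_pileups("A", c(A = 12L), c(G = 2L))
  expect_equal(nrow(call_candidate_snps(thin$sh, thin$yk)), 0)
  lowq <- site_pileups("A", c(A = 12L), c(G = 9L), mapq = 10L)
  expect_equal(nrow(call_candidate_snps(lowq$sh, lowq$yk)), 0)
})

test_that("malformed pileups are rejected", {
  s <- site_pileups("A", c(A = 12L), c(G = 9L))
  unsorted <- dplyr::bind_rows(
    site_pileups("A", c(A = 9L), c(A = 9L), pos = 200L)$sh,
    site_pileups("A", c(A = 9L), c(A = 9L), pos = 100L)$sh)
  expect_error(call_candidate_snps(unsorted, unsorted), "sorted")
  bad <- s$sh
  bad$ref <- "N"
  expect_error(call_candidate_snps(bad, s$yk), "A/C/G/T")
})

test_that("cascade annotates each failed filter from site data alone", {
  het <- apply_cascade(make_candidate("A", "G", c(A = 6L, G = 5L), c(G = 9L)))
  expect_equal(het$filters, "het_within_accession")

  weak <- apply_cascade(make_candidate("A", "G", c(A = 30L), c(G = 2L, A = 18L)))
  expect_setequal(strsplit(weak$filters, ";")[[1]],
                  c("low_alt_reads", "low_alt_fraction"))

  triallelic <- apply_cascade(make_candidate("A", "G", c(C = 10L), c(G = 8L)))
  expect_setequal(strsplit(triallelic$filters, ";")[[1]],
                  c("not_biallelic", "ref_discordant"))

  clean <- apply_cascade(make_candidate("A", "G", c(A = 12L), c(G = 9L)))
  expect_true(clean$pass)

  # annotations depend on rows only: any evaluation order gives one PASS set
  stack <- dplyr::bind_rows(
    make_candidate("A", "G", c(A = 6L, G = 5L), c(G = 9L), pos = 1L),
    make_candidate("A", "G", c(A = 12L), c(G = 9L), pos = 2L),
    make_candidate("A", "G", c(C = 10L), c(G = 8L), pos = 3L))
  fwd <- apply_cascade(stack)
  rev_ <- apply_cascade(stack[3:1, ])
  expect_equal(fwd$filters, rev_$filters[3:1])
})

test_that("alt-fraction scope switch changes the pooled default", {
  # 2 alt reads over 50 pooled (4%) but 2/20 = 10% within the carrier
  cand <- make_candidate("A", "G", c(A = 30L), c(G = 2L, A = 18L))
  pooled <- apply_cascade(cand, filter_config())
  per_acc <- apply_cascade(cand, filter_config(alt_fraction_scope = "per_accession"))
  expect_match(pooled$filters, "low_alt_fraction")
  expect_false(grepl("low_alt_fraction", per_acc$filters))
})

test_that("cluster filter flags windows holding more than the maximum", {
  five <- cluster_filter(calls_at(c(10, 30, 50, 70, 90)))
  expect_true(all(five$filters == "snp_cluster"))
  four <- cluster_filter(calls_at(c(10, 30, 50, 70)))
  expect_true(all(four$pass))
  # window is 100 bp wide: 5 calls spanning 101 bp escape
  wide <- cluster_filter(calls_at(c(10, 30, 50, 70, 110)))
  expect_true(all(wide$pass))
})

test_that("cluster filter equals the exhaustive all-windows oracle", {
  set.seed(20)
  for (i in 1:100) {
    pos <- sort(sample.int(500, sample(1:40, 1)))
    res <- cluster_filter(calls_at(pos))
    expect_identical(grepl("snp_cluster", res$filters), cluster_oracle(pos),
                     info = paste("instance", i))
  }
})

test_that("quality is capped at 999 and defines the high-quality tier", {
  deep <- call_candidate_snps(
    site_pileups("A", c(A = 200L), c(G = 200L))$sh,
    site_pileups("A", c(A = 200L), c(G = 200L))$yk)
  expect_equal(deep$quality, 999)
  expect_equal(deep$tier, "high_quality")
  shallow <- call_candidate_snps(
    site_pileups("A", c(A = 5L), c(G = 3L))$sh,
    site_pileups("A", c(A = 5L), c(G = 3L))$yk)
  expect_lt(shallow$quality, 999)
  expect_equal(shallow$tier, "standard")
})

test_that("VCF round trip preserves calls, including the empty set", {
  path <- withr::local_tempfile(fileext = ".vcf")
  empty <- calls_at(integer(0))
  write_vcf(empty, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "##fileformat=VCFv4.2"))
  expect_equal(sum(!startsWith(lines, "#")), 0)
  expect_equal(nrow(read_vcf(path)), 0)

  one <- calls_at(42)
  write_vcf(one, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 1)
  expect_equal(strsplit(body, "\t")[[1]][7], "PASS")

  cfg <- sim_config(seed = 13, n_genes = 60)
  sim <- simulate_pileups(cfg)
  calls <- call_snps(sim$pileup_sh, sim$pileup_yk)
  write_vcf(calls, path, reference = sim$reference)
  back <- read_vcf(path)
  expect_equal(nrow(back), nrow(calls))
  ord <- order(calls$seq_id, calls$pos)
  for (col in c("seq_id", "pos", "ref_allele", "alt_allele", "quality",
                "filters", "pass", "depth_a1", "depth_a2", "tier"))
    expect_equal(back[[col]], calls[[col]][ord], info = col)
  expect_equal(back$alt_fraction, calls$alt_fraction[ord], tolerance = 1e-4)
})

test_that("written VCF parses under an independent VCF reader", {
  path <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulate_pileups(sim_config(seed = 14, n_genes = 40))
  calls <- call_snps(sim$pileup_sh, sim$pileup_yk)
  write_vcf(calls, path, reference = sim$reference)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(calls))
  expect_setequal(colnames(v@fix)[1:8],
                  c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"))
  expect_true(all(v@fix[, "REF"] %in% c("A", "C", "G", "T")))
})

test_that("concordance counts shared positions and matching alleles", {
  a <- calls_at(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  expect_equal(snp_concordance(a, a)$match_fraction, 1)
  b <- calls_at(c(110, 120))
  expect_equal(snp_concordance(a, b)$shared, 0)
  swapped <- a
  swapped$alt_allele[1] <- "T"      # 1 of 10 alleles swapped
  cc <- snp_concordance(a, swapped)
  expect_equal(cc$shared, 10)
  expect_equal(cc$match_fraction, 0.9)
})

test_that("simulated artifacts are captured by their intended filters", {
  cfg <- sim_config(seed = 21, n_genes = 300, het_artifact_rate = 3e-4,
                    refdisc_artifact_rate = 2e-4, lowfrac_artifact_rate = 2e-4)
  sim <- simulate_pileups(cfg)
  calls <- call_snps(sim$pileup_sh, sim$pileup_yk)
  ck <- paste(calls$seq_id, calls$pos)
  art <- sim$truth$artifact_sites
  intended <- c("heterozygous" = "het_within_accession",
                "cluster" = "snp_cluster",
                "reference-discordant" = "ref_discordant",
                "low-fraction" = "low_alt_reads")
  for (cl in names(intended)) {
    ak <- paste(art$seq_id[art$class == cl], art$pos[art$class == cl])
    hit <- ak[ak %in% ck]
    expect_gt(length(hit), 0)
    rate <- mean(grepl(intended[[cl]], calls$filters[match(hit, ck)]))
    expect_gte(rate, 0.95)
  }
  # no planted artifact survives into the PASS set
  pass_k <- paste(calls$seq_id[calls$pass], calls$pos[calls$pass])
  expect_length(intersect(pass_k, paste(art$seq_id, art$pos)), 0)
})

test_that("clean planted SNPs are fully recovered with high precision", {
  cfg <- sim_config(seed = 22, n_genes = 300)
  sim <- simulate_pileups(cfg)
  calls <- call_snps(sim$pileup_sh, sim$pileup_yk)
  pass <- calls[calls$pass, ]
  depth_ok <- function(tr) {
    k <- paste(tr$seq_id, tr$pos)
    p1 <- sim$pileup_sh[match(k, paste(sim$pileup_sh$seq_id, sim$pileup_sh$pos)), ]
    p2 <- sim$pileup_yk[match(k, paste(sim$pileup_yk$seq_id, sim$pileup_yk$pos)), ]
    p1$depth >= 3 & p2$depth >= 3
  }
  tr <- sim$truth$true_snps[depth_ok(sim$truth$true_snps), ]
  tk <- paste(tr$seq_id, tr$pos)
  pk <- paste(pass$seq_id, pass$pos)
  expect_equal(mean(tk %in% pk), 1)
  expect_gte(mean(pk %in% tk), 0.99)
  # recovered alleles match the planted ones
  m <- match(tk, pk)
  expect_equal(pass$ref_allele[m], tr$ref)
  expect_equal(pass$alt_allele[m], tr$alt)
})
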