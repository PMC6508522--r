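---
title: "Methods: two-accession dark-period transcriptome and metabolome contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-accession dark-period transcriptome and metabolome contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightcontrast)
```

`nightcontrast` implements a comparative pipeline for two substantially
inbred plant accessions ("SH"-like and "YK"-like roles throughout) profiled
during the dark period: SNP calling from paired transcriptome pileups,
replicate-free differential expression with presence–absence classification,
qRT-PCR quantification, F1 heterosis statistics for metabolite panels, and
category-level enrichment of fold changes.  This vignette explains each
model, its assumptions, the tunable parameters, and the design decisions
taken where the procedure left genuine latitude.

## Variant calling for inbred accessions

Both accessions are treated as homozygous at every base, so a true
accession-differentiating SNP looks like two clean, different homozygous
consensus calls.  A candidate is emitted wherever the consensus bases
differ, both depths reach `min_depth` (default 3) and the representative
mapping quality reaches `min_mapq` (default 15).  Only substitutions are
representable; indels never enter the pileup dialect (pyrosequencing-era
data make indel calls unreliable).

The cascade annotates each candidate with every failed rule:

* `het_within_accession` — within either accession the second allele's read
  fraction exceeds `monomorphic_max_minor_fraction` (default 10%) **and**
  the second allele has at least `min_alt_reads` reads.  The read-support
  clause is a deliberate design choice: a fraction-only rule fires on two
  isolated miscalls at depth ~19 (2/19 > 10%), so at realistic error rates
  a fraction-only monomorphism rule destroys recall of perfectly clean
  SNPs while adding no specificity; genuine heterozygosity or misalignment
  always carries several supporting reads.
* `not_biallelic` — more than two alleles at the site once the reference,
  the alternative and any base above the minor-fraction cut in either
  accession are pooled.
* `low_alt_reads`, `low_alt_fraction` — fewer than 3 reads, or under 10% of
  aligned reads, support the alternative allele.  The fraction is evaluated
  over reads pooled across both accessions (the plain reading of "aligned
  reads"); `alt_fraction_scope = "per_accession"` switches to the
  within-carrier variant.
* `ref_discordant` — the accession-1 consensus differs from the reference
  base (the reference genome belongs to the accession-1 role).
* `snp_cluster` — the call sits in some 100-bp window containing strictly
  more than `cluster_max_snps` (default 4) passing candidates.  "More than
  four" is the operative threshold; the count and width are configurable.
  The sliding evaluation over candidate-anchored windows is provably
  equivalent to examining every window start, and the tests compare it
  against that exhaustive oracle.

All annotations are functions of per-site data, so the PASS set is
independent of evaluation order.  Site quality is the Phred-scaled
posterior odds of the two-homozygote difference hypothesis against the
no-difference hypothesis under a symmetric per-read miscall model
(`error_rate` 1e-3), capped at 999; calls at the cap form the
`high_quality` tier.  This reproduces the cap-and-tier behaviour that the
original genotype-likelihood machinery exposes without re-implementing its
full model, which is the only load-bearing aspect downstream.

## Replicate-free differential expression

The count table has one column per accession and no replicates.  Following
the classical no-replicate negative-binomial contract:

1. **Normalization.** Median-of-ratios size factors: each column's median
   ratio to the per-gene geometric-mean pseudo-reference, over genes
   positive in both columns.  The literal arithmetic median is used; it
   differs from a geometric interpolation of the middle pair only when the
   gene count is even, and at most in the seventh decimal on realistic
   tables.
2. **Blind dispersion.** The two columns are treated as replicates of one
   condition and a method-of-moments dispersion is computed per gene; a
   mean–dispersion trend α(μ) = a₀ + a₁/μ is then fitted by an iterative
   gamma-family GLM.  With only two samples the per-gene estimates have one
   degree of freedom, and on weakly dispersed data the parametric form is
   ill-conditioned (the asymptote is driven negative); the fit then falls
   back to a local regression of log dispersion on log mean
   (fit-only sharing; floor 1e-8).  Both paths are exposed via `fit_type`.
3. **Exact conditional test.** For a gene with counts (k₁, k₂), the
   p-value is the probability, under independent NB laws with equal
   normalized mean, the fitted dispersion and the observed size factors, of
   all splits of k₁ + k₂ whose probability does not exceed that of the
   observed split.  Identical columns therefore give p = 1 exactly, and the
   test is invariant to swapping the accession labels.
4. **FDR.** Benjamini–Hochberg adjustment; calls at `padj <= 0.2`, the
   operating point of the emulated analysis.

Reported folds are raw-count log2(YK/SH) — the published fold column is
reproduced by raw, not normalized, ratios — rounded half-away-from-zero to
one decimal for display; genes with zero counts in one accession are
labelled "Absent in SH/YK" rather than given an infinite fold.
Presence–absence variation (PAV) is exactly that zero-in-one-accession
condition, summarized as a fraction of genes detected anywhere.

## qRT-PCR quantification

Primer efficiency comes from a five-point fivefold dilution series: CT is
regressed on log10(relative concentration) (log10 is required for the
standard efficiency formula to give 100% at slope −3.32), technical
replicates are averaged per dilution point first (reducing the leverage of
single outlier wells), and E = 10^(−1/slope) − 1 with an inclusive pass
band of 80–110% and a negative-slope requirement.  Relative expression is
(1+E)^(−ΔCT) with ΔCT = CT,target − CT,reference.  "No amplification" is a
missing CT, never CT = 0.  Cross-platform concordance with RNA-seq uses
only the direction of change, with absence labels matched to
no-amplification flags; direction is robust to whether the qPCR folds are
ratios of relative expression.

## Metabolite statistics and heterosis

The input is a long table of internal-standard-normalized relative
concentrations: two experiments, genotypes SH/YK (both) and F1 (experiment
2 only), n = 4 and n = 3 replicates respectively.

* **Parental contrasts.** Two-tailed two-sample t tests per experiment,
  pooled variance by default (the classical reading of "t test" at n =
  3–4), Welch behind a switch.  Groups with no variance at all are flagged
  untestable rather than given p = 0; equal constant groups give p = 1.
* **Three-genotype comparisons.** One-way ANOVA with Tukey's studentized
  range test, familywise-adjusted.
* **Combined analysis.** A fixed-effects two-factor ANOVA over both
  experiments with experiment and genotype as main effects and no
  interaction — the additive model matches the described design; a
  genotype-within-experiment nesting is available behind `nested = TRUE`.
  Only genotypes present in both experiments (the parents) enter.
* **Mid-parent test.** One-sample t of the F1 replicates against the
  constant mid-parent mean, using only the F1 variance (df = n_F1 − 1).
  The mid-parent value is computed from the experiment that contains the
  F1.
* **Transgression.** A metabolite is transgressive-high (low) when the F1
  mean exceeds the high parent (falls below the low parent) and a
  two-sample t against that extreme parent reaches p ≤ .05; the reported
  ratio is F1/high-parent or low-parent/F1.  Metabolites undetected in one
  parent are reported separately.
* **Mode classification.** Transgressive when labelled; otherwise dominant
  when the F1 differs from exactly one parent, additive when it differs
  from both (it sits between them) or neither, with the mid-parent test as
  the tiebreaker for parentally equivalent metabolites.
* **Panel-level tests.** A two-sided exact binomial test of
  negative-versus-positive transgression among both-parent metabolites,
  and a 2×2 chi-squared test (no continuity correction by default)
  associating parental difference (t test at p ≤ .05 in the F1 experiment)
  with heterosis — in either its transgressive or its
  mid-parent-deviation reading, since "heterosis" is ambiguous between the
  two; both are exposed and the fraction of metabolites below the
  mid-parent value is reported both as a raw mean comparison and as a
  significant-deviation count.
* **Starch proxy.** The SH/YK ratio of maltose + glucose mean
  concentrations summed over both experiments, displayed at one decimal.

No multiple-testing correction is applied across metabolites, matching the
star-annotation convention; a BH column is emitted as supplementary output
only.

### Calibration

The type-I error battery (10,000 null replicates per test, run in the
acceptance suite) covers the t- and F-based tests: the parental t, the
mid-parent t, the combined-ANOVA genotype F, and the Tukey familywise
rate, each expected in [0.04, 0.06] at α = .05.  The transgressive *label*
is excluded by design: it conditions a two-sided test on a directional
excursion, so its null label rate is near α/2, not α.  The exact binomial
and chi-squared tests are discrete and cannot hold a [0.04, 0.06] size at
these panel sizes; they are instead verified against closed-form oracles.

## Category enrichment

For each category with at least `min_size` (default 3) members, the member
log2 folds are tested for divergence from an even up/down split by a
two-sided Wilcoxon signed-rank test against zero — the test named by the
emulated pathway-analysis convention; a rank-sum mode (members versus
non-members, the variant some pathway tools historically used) is behind a
flag.  Zeros are dropped, ties get midranks, and for n ≤ 25 the null
distribution of W is computed exactly by convolving the sign-flip
generating function over the doubled (hence integral) midranks — valid
under ties, where tabulated exact distributions are not.  Above n = 25 a
normal approximation with continuity correction is used; the two modes
agree within 0.01 at the crossover.  P-values are reported uncorrected, as
the convention dictates; the BH column drives no calls.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates; every
downstream property test and the acceptance script run on its output with
planted ground truth.

* **Pileups.** Two accessions diverging at `snp_rate` = 1e-4 per bp (one
  SNP per 10 kb of transcript), Poisson depth with mean 20 (the per-site
  depth of the emulated run is unstated; 20 is a realistic transcriptome
  coverage and is configurable), uniform miscalls at 0.5% (within the
  0.5–1% range typical of pyrosequencing substitutions).  Artifact
  plantings: ~50/50 heterozygous sites, thin 2-read variants at depth 4,
  reference-discordant sites, and 5–7-SNP clusters confined to one 100-bp
  window, each recorded in the ground truth with its class.  True SNPs
  within 100 bp of a planted cluster are suppressed so recall is
  well-defined.
* **Counts.** Lognormal baseline means scaled to ~1 M total reads across
  ~18 k genes by default; NB dispersion 0.02 (two inbred lines measured
  once; residual technical plus accession noise); 18.5% planted
  presence–absence genes split evenly between accessions; planted log2
  folds restricted to genes with baseline mean ≥ 20, because a planted
  fold on a near-zero gene is unobservable at this depth and the emulated
  candidates are all reasonably covered.
* **Metabolome.** 144 metabolites, n = 4 / n = 3 replicates, lognormal
  replicate noise with CV 10%, and a per-metabolite lognormal(σ = 0.3)
  multiplicative shift between experiments (cross-experiment differences
  are environmental and unquantified; 0.3 gives visible but
  rank-preserving shifts).  Heterosis modes are drawn from
  `heterosis_mix = (additive .50, dominant .34, transgressive-up .01,
  transgressive-down .15)`, chosen a priori so the implied fraction of F1
  means below mid-parent (0.5 + (down − up)/2 ≈ 0.57) and the strongly
  negative transgression direction match the emulated study's headline
  fractions.  Parental separation for additive and dominant metabolites is
  |log2 ratio| ~ U(1.5, 2): dominance is only defined when the parents
  differ, and at CV 10% with n = 3 this separation is what makes the three
  modes statistically distinguishable (a power analysis at these settings
  puts every per-mode recovery above 0.85).  Transgressive metabolites
  keep equal parents with probability 0.75, planting the association
  between transgression and parentally equivalent metabolites.
  Transgressive F1 means sit 50% beyond the extreme parent.  A small
  fraction (4/144) of metabolites is undetected in one parent.
* **qPCR.** Five fivefold dilutions, three wells each, CT = intercept +
  slope·log10(conc) + N(0, 0.2); sample CTs back-computed from planted
  expression ratios through the true efficiency.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and mapping artifacts beyond the four
planted classes, positional error profiles, isoform structure, the
low-abundance skew of real presence–absence genes (real single-accession
genes are mostly near the detection limit, so a real DEG list contains far
fewer PAV genes than this generator's), metabolite detection differences
between experiments, and any genotype-by-environment interaction.

## Numerical choices

Display folds round half-away-from-zero to one decimal (matching the
published convention for values like −5.5).  The exact NB test compares
log-probabilities with a 1e-7 additive tie tolerance.  Dispersions are
floored at 1e-8.  Consensus ties in a pileup column resolve to the
first base in A<C<G<T order (deterministic, and at realistic depths ties
are error-dominated sites that fail the cascade anyway).  The efficiency
pass band is inclusive within 1e-9 to keep the printed 80/110 boundaries
boundary-inclusive under floating-point round-trip.  Problem sizes in the
test and acceptance runs — 1,000-gene pileups for cascade properties,
600-gene tables across 50 seeds for DE recall, 10,000 replicates for the
type-I battery, three 144-metabolite panels for mode recovery — are the
package's chosen operating points balancing statistical resolution against
a desk-scale run.

## Known limitations

The quality tier reproduces only the cap-at-999 behaviour, not the full
genotype-likelihood model, so tier fractions are not comparable to
pipelines using the original caller.  The no-replicate test inherits the
classical limitation that biological accession-by-environment variance is
unidentifiable from two columns; its FDR guarantee is conditional on the
fitted dispersion trend.  The enrichment test treats category members as
exchangeable and ignores inter-gene correlation.  Dataset-level counts
(total SNPs, expressed genes, alignment rates) depend on raw sequencing
data and are out of scope.
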