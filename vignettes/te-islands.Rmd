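---
title: "Detecting TE islands and measuring intragenomic divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE islands and measuring intragenomic divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teislandr)
```

## The problem

Some genomes — the small genome of the inbred, invasive ant
*Cardiocondyla obscurior* is the motivating case — do not scatter their
transposable elements (TEs) uniformly. Instead, TEs pile up in a handful
of well-defined "TE islands" embedded in otherwise low-density regions
(LDRs). Those islands behave like a distinct sub-genome: they diverge
faster between populations (more SNVs, more copy-number changes, spurious
heterozygous calls from collapsed duplications), their genes are
CpG-depleted (a methylation footprint) and weakly expressed, and
particular repeat superfamilies are over-represented in them.

`teislandr` implements that analysis as a reusable, tested pipeline:

1. **Island calling** from sliding-window TE annotation density
   (`tile_windows()`, `aggregate_windows()`, `call_te_islands()`).
2. **Between-lineage divergence** of the two compartments: pooled
   coverage-ratio deviations (`coverage_ratio_windows()`,
   `region_deviation_summary()`), SNV region summaries
   (`snv_region_summary()`), classification of heterozygous calls into
   true heterozygotes versus collapsed duplications
   (`classify_het_snvs()`), coding-effect annotation and dN/(dN+dS)
   (`annotate_snv_effect()`, `gene_dn_ds()`), and CNV candidate flagging
   (`flag_cnv_candidates()`).
3. **Composition statistics**: repeat-superfamily and gene-set enrichment
   by two-sided Fisher tests with Benjamini–Hochberg FDR
   (`superfamily_enrichment()`, `term_enrichment_two_tailed()`), TE length
   polymorphism by Mann–Whitney U (`length_polymorphism()`).
4. **CpG and expression**: gene-body CpG observed/expected ratios
   (`cpg_oe()`, `gene_exon_cpg_oe()`), a between-lineage o/e ratio
   variance F-test (`lineage_oe_ratio_test()`), median-of-ratios
   size-factor normalisation and regional expression comparisons
   (`size_factors()`, `mean_normalized_expression()`,
   `compare_region_expression()`, `expression_rank_curve()`).
5. A **synthetic-genome generator** with planted ground truth
   (`simulate_genome()` and friends) and a recovery harness
   (`recovery_study()`, `check_recovery()`).

## The island-calling procedure

TE and exon annotations are counted into non-overlapping 1 kb windows.
Overlapping TE annotations are union-merged first, so `te_bp` can never
exceed the window length; this also makes the per-scaffold window sums
equal the length of the union of the clipped TE features (a conservation
property the tests verify against a per-base bitmap).

The 1 kb track is then aggregated into 200 kb windows sliding in 1 kb
steps, on scaffolds of at least 200 kb (`min_scaffold`). Islands are
seeded by windows whose TE bp lies in the closed upper 5% tail: the
threshold is the empirical type-7 quantile (default `quantile = 0.95`) of
TE bp over **all** eligible-scaffold windows, and qualification uses
`>=`. Computing one global threshold, rather than one per scaffold, is
what lets islands concentrate on a few TE-dense scaffolds; a per-scaffold
mode exists behind the `per_scaffold` flag for comparison. Windows with
zero TE bp never qualify, whatever the quantile says.

Qualifying windows are unioned per scaffold into maximal intervals. A
200 kb sliding window smears island edges by up to one window span, so
edges are refined at 1 kb resolution: terminal 1 kb tiles whose TE
fraction is below the global median 1 kb TE fraction are trimmed from
both ends. When TE density outside islands is so low that the median 1 kb
TE fraction is 0 (true of the default synthetic genomes), trimming is a
no-op and island calls carry up to ~20 kb of slack per edge — visible as
a planted-island Jaccard around 0.85–0.9 rather than 1.0. Intervals
shorter than `min_island` (default 10 kb, deliberately permissive) are
dropped; the remainder of every eligible scaffold is LDR. Islands smaller
than the window span cannot be resolved reliably; for genomes with small
islands the `span` parameter should be scaled down (the pipeline tests do
exactly that for 80 kb islands).

All downstream region assignment uses the midpoint rule: a feature, gene,
window or SNV belongs to the compartment containing its midpoint, which
is unambiguous for records straddling an island edge. Base-pair tallies
(`tally_superfamilies()`, `island_summary()`) split bp exactly at island
boundaries instead.

## Divergence statistics and their conventions

* **Coverage ratios** are oriented lineage A / lineage B (BR/JP in the
  motivating study). Windows with mean depth below `min_depth = 5` in
  either lineage are masked: ratios at negligible coverage reflect
  mapping artifacts. The deviation is `d = |r / centre - 1|` with the
  centre the genome-wide **median** unmasked ratio by default (robust to
  CNV outliers); the mean is available via `center = "mean"`.
* **Heterozygous-call classification**: in pooled haploid males true
  heterozygous calls should be rare; a het call at depth at least
  `fold_threshold = 1.5` times the lineage median depth (boundary
  inclusive) is labelled a collapsed duplication. The twofold coverage of
  a collapsed locus is the signature; 1.5 sits in the valley between the
  1x and 2x modes of the het-call coverage distribution.
* **CNV candidates** are unmasked 1 kb windows with `d >=
  deviation_threshold` (default 0.5 — the study picked loci by visual
  inspection, so no published cutoff exists), merged when adjacent and
  ranked by peak deviation.
* **Coding effects** translate the codon containing the site under the
  standard nuclear code, reverse-complemented for minus-strand genes.
  Genes whose CDS length is not a multiple of 3, codons containing `N`,
  and sites whose VCF reference allele disagrees with the assembly are
  all `unknown` rather than guessed.
* **Fisher two-sided p** follows the probability-mass rule: the sum of
  hypergeometric probabilities (same margins) not exceeding the observed
  table's probability, with a 1e-7 relative tie tolerance. Two-sided
  conventions differ between implementations, so this is pinned down and
  tested against full enumeration. "Two-tailed" term enrichment means
  both over- and under-represented units are reported from that test.
* **Mann–Whitney U** uses midranks; p is exact (Wilcoxon distribution)
  when both samples have at most 20 observations and no ties, otherwise a
  normal approximation with tie-corrected variance and continuity
  correction. Samples entirely tied with each other give p = 1.
* **CpG o/e** is `n_CpG * L / (n_C * n_G)` with an overlapping scan; `N`
  bases are excluded from all counts and from `L`. Gene profiles count
  per exon and sum, so a CpG spanning an exon junction is not counted —
  this keeps the statistic independent of exon order.
* **Size factors** are classic median-of-ratios: geometric-mean reference
  over genes with no zero count, per-sample median of count/reference.
  Rescaling one library by `c` moves its factor by `c^((m-1)/m)` and the
  normalised matrix by a single global constant; tests assert both.
  Expression rank percentiles (0 = least expressed) are defined over
  genes with nonzero total normalised count; fully unexpressed genes are
  reported separately.

## What the synthetic genomes emulate

`sim_params()` defaults describe the planted study conditions: three 2 Mb
scaffolds; two 300 kb islands; TE occupancy 0.45 inside islands versus
0.05 outside (copies placed without overlap, so the realised union
fraction tracks the nominal density); island copies drawn longer
(lognormal, median ~3 kb vs ~0.8 kb); eight superfamilies with two
island-biased ones; ~0.1 genes per kb avoiding >= 50% TE overlap, with
valid reading frames (ATG start, sense body, terminal stop) spread over
2–5 exons; homozygous SNVs at 2/kb in islands vs 0.5/kb in LDRs; rare
background heterozygous calls plus dense spurious het calls inside four
planted 10 kb collapsed duplications (doubled coverage in one random
lineage); 60x Poisson coverage per lineage; a negative-binomial 7 queen +
7 larva expression design with island gene means scaled by 0.02 and a 3x
queen-specific boost for island genes.

Two structural choices encode the regulatory biology:

* **Coverage-ratio noise.** Each 1 kb block gets an independent
  lineage-specific lognormal mappability factor, sd 0.18 in islands and
  0.08 in LDRs. This emulates multi-mapping noise and TE
  presence/absence divergence around repeats, and gives islands a
  reliably higher median ratio deviation. The sds are kept small enough
  that a collapsed duplication's twofold coverage still clears the
  1.5-fold classification threshold in well over 90% of planted sites;
  pushing island noise toward the absolute deviation levels seen on real
  data would trade that recall away, and absolute deviation levels are
  not a target of the synthetic study.
* **CpG–expression coupling.** Each gene has a latent expression score.
  LDR genes convert CG -> TG (the deamination footprint of germline
  methylation) at a rate increasing with expression, up to 0.2; island
  genes convert at a rate decreasing with expression, up to 0.7.
  Conversions that would create an internal stop codon are skipped. This
  reproduces the study's qualitative pattern — island genes CpG-depleted
  overall, o/e falling with expression in LDRs but rising in islands —
  without modelling methylation itself.

What the generator does **not** emulate: real TE sequence content
(TE intervals are annotation-only; sequence matters only inside gene
exons), read-level error and mapping models, indels, assembly gaps,
GC-content variation, linked selection. Passing recovery tests therefore
show the pipeline recovers planted structure of the stated kind and
effect size; they are not evidence about behaviour under assembly
artifacts or annotation error beyond the modelled noise.

## Problem sizes and numerical choices

The recovery study (`recovery_study()`, also run by
`scripts/acceptance.R`) uses 20 seeds at the default 3 x 2 Mb scale —
about 120 Mb of simulated per-base coverage in total — which keeps a full
run in the minutes range on one core. Unit tests use scaled-down genomes
(2 x 0.4 Mb, one 80 kb island, `span = 20000`) where the full conditions
are not the point of the test. Quantiles are type-7 (R's default);
Fisher tie comparison uses a 1e-7 relative tolerance; the conditional
odds ratio is solved in log space to ~1e-10; degenerate cases (zero
margins, all-tied samples, zero variances, empty compartments) return
flagged values (`degenerate`, `skipped`, `undefined_region`) rather than
NA-propagating silently.

## Known limitations

* Island boundaries inherit up to ~`span`/10 of slack when the LDR TE
  density is too low for median-fraction trimming to engage.
* The 95% quantile is computed on TE bp of full windows; on fractions it
  would differ only for partial windows, which are never emitted.
* dN/(dN+dS) is a per-gene SNV count ratio, not a substitution-model
  estimate; it is the right scale for ranking compartments, not for
  absolute selection inference.
* `lineage_oe_ratio_test()` assumes units are matched one-to-one across
  lineages and tests variance ratios only.
* The enrichment analyses on copy counts and base counts are reported
  separately and not corrected jointly.

## A minimal run

```{r example, eval = FALSE}
params <- sim_params(seed = 1)
dir <- tempfile("teislands_")
ds <- simulate_dataset(params, file.path(dir, "data"))
config <- list(
  inputs = list(
    fasta = ds$fasta, gff = ds$gff, vcf = ds$vcf,
    depth = list(BR = ds$depth[["BR"]], JP = ds$depth[["JP"]]),
    counts = ds$counts, groups = ds$groups
  ),
  params = list()
)
report <- run_pipeline(config, file.path(dir, "out"))
check_recovery(file.path(dir, "data"), file.path(dir, "out"))
```
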