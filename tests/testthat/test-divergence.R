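test_that("coverage ratios are 1 for identical tracks and masked at low depth", {
  d <- depth_rows("s1", 1:3000, rep(20L, 3000))
  rw <- coverage_ratio_windows(d, d |> dplyr::mutate(lineage = "JP"),
                               c(s1 = 3000))
  expect_true(all(rw$ratio == 1))
  expect_true(all(rw$deviation == 0))
  expect_false(any(rw$masked))

  # window 3 has depth 2 < min_depth in lineage B -> masked
  db <- depth_rows("s1", 1:3000, rep(c(20L, 20L, 2L), each = 1000), "JP")
  rw2 <- coverage_ratio_windows(d, db, c(s1 = 3000), min_depth = 5)
  expect_equal(rw2$masked, c(FALSE, FALSE, TRUE))
  expect_true(is.na(rw2$deviation[3]))

  expect_error(
    coverage_ratio_windows(d, depth_rows("s1", 1:3000, rep(0L, 3000), "JP"),
                           c(s1 = 3000)),
    "unmasked"
  )
})

test_that("deviation is |ratio/median - 1| with a hand-checked median", {
  # three windows with ratios 1, 1, 2 -> median 1, deviations 0, 0, 1
  da <- depth_rows("s1", 1:3000, rep(c(20L, 20L, 40L), each = 1000))
  db <- depth_rows("s1", 1:3000, rep(20L, 3000), "JP")
  rw <- coverage_ratio_windows(da, db, c(s1 = 3000))
  expect_equal(rw$ratio, c(1, 1, 2))
  expect_equal(rw$deviation, c(0, 0, 1))
  expect_equal(attr(rw, "center_ratio"), 1)
  # mean normalisation by flag: mean ratio 4/3
  rwm <- coverage_ratio_windows(da, db, c(s1 = 3000), center = "mean")
  expect_equal(attr(rwm, "center_ratio"), 4 / 3)
})

test_that("regional deviation medians and undefined compartments", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1L,
                                       end = 2000L), c(s1 = 6000))
  # island windows deviate (ratio 2), the four LDR windows do not, so the
  # genome-wide median ratio is 1
  da <- depth_rows("s1", 1:6000, rep(c(40L, 40L, 20L, 20L, 20L, 20L), each = 1000))
  db <- depth_rows("s1", 1:6000, rep(20L, 6000), "JP")
  rw <- coverage_ratio_windows(da, db, c(s1 = 6000))
  rs <- region_deviation_summary(rw, part)
  expect_equal(rs$median_islands, 1)
  expect_equal(rs$median_ldr, 0)

  empty <- toy_partition(tibble::tibble(scaffold = character(),
                                        start = integer(), end = integer()),
                         c(s1 = 6000))
  rs0 <- region_deviation_summary(rw, empty)
  expect_true(is.na(rs0$median_islands))
  expect_equal(rs0$undefined_region, "island")
})

test_that("het SNVs are classified by fold coverage with inclusive boundary", {
  s <- dplyr::bind_rows(
    snv_rows("s1", 10, zygosity = "het", depth = 120),
    snv_rows("s1", 20, zygosity = "het", depth = 60),
    snv_rows("s1", 30, zygosity = "het", depth = 90),
    snv_rows("s1", 40, zygosity = "hom_alt", depth = 55),
    snv_rows("s1", 50, zygosity = "het", depth = 0)
  )
  cls <- classify_het_snvs(s, "BR", median_depth = 60, fold_threshold = 1.5)
  expect_equal(cls$label,
               c("collapsed_duplication", "true_het", "collapsed_duplication",
                 "hom", "masked"))
  expect_equal(cls$fold[1], 2.0)
  expect_error(classify_het_snvs(s, "BR", 60, fold_threshold = -1),
               "non-negative")
})

test_that("SNV region summary counts and fractions add up", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1000L,
                                       end = 1999L), c(s1 = 10000))
  # 3 of 12 sites in the island
  pos <- c(1100, 1500, 1900, seq(3000, 9000, length.out = 9))
  s <- dplyr::bind_rows(
    snv_rows("s1", pos, "BR", "hom_alt"),
    snv_rows("s1", pos, "JP", "hom_ref")
  )
  rs <- snv_region_summary(s, part)
  expect_equal(rs$overall$pct_islands, 25)
  expect_equal(rs$overall$n_sites, 12)
  bc <- rs$by_class
  expect_true(all(bc$n_islands + bc$n_ldr + bc$n_unassigned == bc$n_total))
})

test_that("coding-effect annotation translates codons on both strands", {
  # plus strand: CDS 4..12 = GCT GCA TAA after ATG? Keep it explicit:
  # sequence: pos 1..12 : ATG GCT CAT TAA (start, Ala, His, stop)
  seq <- "ATGGCTCATTAA"
  scaff <- tibble::tibble(scaffold = "s1", length = 12L, sequence = seq)
  f <- dplyr::bind_rows(
    feature_row("s1", 1, 12, "gene", id = "g1"),
    feature_row("s1", 1, 12, "exon", parent = "g1"),
    feature_row("s1", 1, 12, "cds", parent = "g1")
  )
  gm <- gene_models(f)
  # GCT -> GCC at pos 6 (third codon position): synonymous (Ala)
  s_syn <- snv_rows("s1", 6, ref = "T", alt = "C")
  # GCT -> GAT at pos 5 (second position): nonsynonymous (Ala -> Asp)
  s_non <- snv_rows("s1", 5, ref = "C", alt = "A")
  ann <- annotate_snv_effect(dplyr::bind_rows(s_syn, s_non), gm, scaff)
  expect_equal(ann$effect[ann$pos == 6], "synonymous")
  expect_equal(ann$effect[ann$pos == 5], "nonsynonymous")

  # minus strand gene: genomic seq = revcomp(ATGGCTCATTAA) = TTAATGAGCCAT
  scaff2 <- tibble::tibble(scaffold = "s2", length = 12L,
                           sequence = "TTAATGAGCCAT")
  f2 <- dplyr::bind_rows(
    feature_row("s2", 1, 12, "gene", id = "g2", strand = "-"),
    feature_row("s2", 1, 12, "exon", parent = "g2", strand = "-"),
    feature_row("s2", 1, 12, "cds", parent = "g2", strand = "-")
  )
  gm2 <- gene_models(f2)
  # genomic pos 7 is the complement of transcript pos 6 (G in AGC = rc of GCT)
  s2 <- snv_rows("s2", 7, ref = "A", alt = "G")  # transcript T -> C, synonymous
  ann2 <- annotate_snv_effect(s2, gm2, scaff2)
  expect_equal(ann2$effect, "synonymous")

  # intronic site is noncoding
  f3 <- dplyr::bind_rows(
    feature_row("s1", 1, 12, "gene", id = "g3"),
    feature_row("s1", 1, 6, "exon", parent = "g3"),
    feature_row("s1", 10, 12, "exon", parent = "g3"),
    feature_row("s1", 1, 6, "cds", parent = "g3"),
    feature_row("s1", 10, 12, "cds", parent = "g3")
  )
  ann3 <- annotate_snv_effect(snv_rows("s1", 8, ref = "A", alt = "C"),
                              gene_models(f3), scaff)
  expect_equal(ann3$effect, "noncoding")

  # incomplete CDS frame -> unknown
  f4 <- dplyr::bind_rows(
    feature_row("s1", 1, 12, "gene", id = "g4"),
    feature_row("s1", 1, 11, "exon", parent = "g4"),
    feature_row("s1", 1, 11, "cds", parent = "g4")
  )
  ann4 <- annotate_snv_effect(snv_rows("s1", 5, ref = "C", alt = "A"),
                              gene_models(f4), scaff)
  expect_equal(ann4$effect, "unknown")
})

test_that("effect annotation agrees with full-CDS retranslation", {
  # brute-force oracle: substitute the allele into the scaffold, re-splice
  # the CDS, translate the whole protein and compare with the reference
  oracle_effect <- function(snv, gene, scaff_seq) {
    cds <- gene$cds[[1]]
    splice <- function(seq) {
      s <- paste(stringr::str_sub(seq, cds$start, cds$end), collapse = "")
      if (gene$strand == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      s
    }
    mut <- scaff_seq
    stringr::str_sub(mut, snv$pos, snv$pos) <- snv$alt
    p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(splice(scaff_seq)),
                                                if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
    p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(splice(mut)),
                                                if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
    if (identical(p_ref, p_alt)) "synonymous" else "nonsynonymous"
  }

  p <- small_sim_params(seed = 21, hom_snv_per_kb = c(island = 4, ldr = 4),
                        gene_per_kb = 0.2)
  g <- simulate_genome(p)
  sv <- simulate_snvs(g, p)
  gm <- gene_models(g$features)
  ann <- annotate_snv_effect(sv$snvs, gm, g$scaffolds)
  ann <- dplyr::distinct(
    ann[ann$effect %in% c("synonymous", "nonsynonymous"), ],
    scaffold, pos, ref, alt, effect, gene_id
  )
  expect_gt(nrow(ann), 50)
  seqs <- setNames(g$scaffolds$sequence, g$scaffolds$scaffold)
  for (i in seq_len(min(nrow(ann), 60))) {
    gene <- gm[gm$gene_id == ann$gene_id[i], ]
    expect_equal(
      ann$effect[i],
      oracle_effect(ann[i, ], gene, seqs[[ann$scaffold[i]]]),
      info = sprintf("%s:%d", ann$scaffold[i], ann$pos[i])
    )
  }
})

test_that("per-gene dN/(dN+dS) and regional synonymous rates", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1L,
                                       end = 1000L), c(s1 = 10000))
  genes <- tibble::tibble(
    gene_id = c("gi", "gl", "g0"), scaffold = "s1",
    strand = "+",
    start = c(100L, 5000L, 7000L), end = c(400L, 5300L, 7300L),
    exons = list(tibble::tibble(start = 100L, end = 400L),
                 tibble::tibble(start = 5000L, end = 5300L),
                 tibble::tibble(start = 7000L, end = 7300L)),
    cds = list(tibble::tibble(start = 100L, end = 400L),
               tibble::tibble(start = 5000L, end = 5300L),
               tibble::tibble(start = 7000L, end = 7300L)),
    cds_len = 301L, cds_complete = FALSE
  )
  ann <- dplyr::bind_rows(
    snv_rows("s1", c(150, 200, 250, 300)) |>
      dplyr::mutate(effect = c("nonsynonymous", "nonsynonymous",
                               "nonsynonymous", "synonymous"),
                    gene_id = "gi"),
    snv_rows("s1", c(5100, 5150, 5200, 5250)) |>
      dplyr::mutate(effect = c("nonsynonymous", "synonymous", "synonymous",
                               "synonymous"),
                    gene_id = "gl")
  )
  res <- gene_dn_ds(ann, genes, part)
  pg <- res$per_gene
  expect_equal(pg$fraction[pg$gene_id == "gi"], 0.75)
  expect_equal(pg$fraction[pg$gene_id == "gl"], 0.25)
  expect_true(is.na(pg$fraction[pg$gene_id == "g0"]))  # dN+dS = 0, excluded
  expect_equal(res$comparison$n_islands, 1)
  expect_equal(res$comparison$n_ldr, 1)
  syn <- res$syn_per_kb
  expect_equal(syn$syn_per_kb[syn$region == "island"], 1 / 0.301)
  expect_equal(syn$syn_per_kb[syn$region == "ldr"], 3 / 0.602)
})

test_that("CNV candidates are thresholded, merged and gene-annotated", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1L,
                                       end = 2000L), c(s1 = 6000))
  # ratios per window: 2, 2, 1, 1, 1, 1 -> median 1, d = 1,1,0,0,0,0
  da <- depth_rows("s1", 1:6000, rep(c(40L, 40L, 20L, 20L, 20L, 20L), each = 1000))
  db <- depth_rows("s1", 1:6000, rep(20L, 6000), "JP")
  rw <- coverage_ratio_windows(da, db, c(s1 = 6000))
  genes <- tibble::tibble(gene_id = "gA", scaffold = "s1",
                          start = 1500L, end = 2500L)
  cand <- flag_cnv_candidates(rw, genes, part, deviation_threshold = 0.5)
  expect_equal(nrow(cand), 1)  # two adjacent windows merged
  expect_equal(cand$start, 1L)
  expect_equal(cand$end, 2000L)
  expect_equal(cand$genes, "gA")
  expect_equal(cand$region, "island")

  none <- flag_cnv_candidates(
    coverage_ratio_windows(db |> dplyr::mutate(lineage = "BR"), db,
                           c(s1 = 6000)),
    genes, part, deviation_threshold = 0.5
  )
  expect_equal(nrow(none), 0)
})
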