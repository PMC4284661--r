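test_that("simulation is deterministic given the seed", {
  p <- small_sim_params(seed = 42)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1$scaffolds, g2$scaffolds)
  expect_identical(g1$features, g2$features)
  expect_identical(g1$truth$islands, g2$truth$islands)
  expect_identical(simulate_snvs(g1, p)$snvs, simulate_snvs(g2, p)$snvs)
  expect_identical(simulate_counts(g1, p)$counts,
                   simulate_counts(g2, p)$counts)
  g3 <- simulate_genome(small_sim_params(seed = 43))
  expect_false(identical(g1$scaffolds$sequence, g3$scaffolds$sequence))
})

test_that("realised island TE fraction tracks the nominal density", {
  p <- small_sim_params(seed = 2, te_density = c(island = 0.5, ldr = 0.05))
  g <- simulate_genome(p)
  isl <- g$truth$islands
  te <- g$features[g$features$kind == "te_copy" &
                     g$features$scaffold == isl$scaffold[1], ]
  part <- toy_partition(isl[, c("scaffold", "start", "end")],
                        setNames(g$scaffolds$length, g$scaffolds$scaffold))
  tal <- tally_superfamilies(g$features, part)
  frac <- sum(tal$bp_islands) / (isl$end[1] - isl$start[1] + 1)
  expect_lt(abs(frac - 0.5), 0.1)

  g0 <- simulate_genome(small_sim_params(
    seed = 2, te_density = c(island = 0, ldr = 0)
  ))
  expect_false("te_copy" %in% g0$features$kind)
  expect_error(simulate_genome(small_sim_params(
    seed = 2, te_density = c(island = 1.5, ldr = 0)
  )), "\\[0, 1\\]")
})

test_that("planted genes carry valid reading frames and island CpG depletion", {
  p <- small_sim_params(seed = 6)
  g <- simulate_genome(p)
  gm <- gene_models(g$features)
  expect_true(all(gm$cds_complete))
  seqs <- setNames(g$scaffolds$sequence, g$scaffolds$scaffold)
  # spot-check 10 genes: ATG start, no internal stop, stop at the end
  idx <- seq_len(min(10, nrow(gm)))
  for (i in idx) {
    cds <- gm$cds[[i]]
    s <- paste(stringr::str_sub(seqs[[gm$scaffold[i]]], cds$start, cds$end),
               collapse = "")
    if (gm$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("coverage has the right mean and doubled duplications", {
  p <- small_sim_params(seed = 13)
  g <- simulate_genome(p)
  cov <- simulate_coverage(g, p)
  expect_named(cov, c("BR", "JP"))
  # genome-wide mean within depth +- 1 (LDR noise is mild and symmetric)
  expect_lt(abs(mean(cov$BR$depth) - p$depth), 1.5)
  d <- g$truth$duplications[1, ]
  cv <- cov[[d$lineage]]
  other <- cov[[setdiff(p$lineages, d$lineage)]]
  sel <- cv$scaffold == d$scaffold & cv$pos >= d$start & cv$pos <= d$end
  ratio <- mean(cv$depth[sel]) / mean(other$depth[sel])
  expect_lt(abs(ratio - 2), 0.25)

  cov0 <- simulate_coverage(g, small_sim_params(seed = 13, depth = 0))
  expect_true(all(cov0$BR$depth == 0))
})

test_that("SNV placement follows region rates and duplication structure", {
  p <- small_sim_params(seed = 23)
  g <- simulate_genome(p)
  sv <- simulate_snvs(g, p)
  tr <- sv$truth
  isl <- g$truth$islands
  isl_kb <- sum(isl$end - isl$start + 1) / 1000
  ldr_kb <- sum(g$scaffolds$length) / 1000 - isl_kb
  hom <- tr[tr$true_class == "divergence", ]
  n_isl <- sum(hom$region == "island")
  n_ldr <- sum(hom$region == "ldr")
  # realized counts within 3 sigma of the Poisson expectation
  expect_lt(abs(n_isl - 2 * isl_kb), 3 * sqrt(2 * isl_kb))
  expect_lt(abs(n_ldr - 0.5 * ldr_kb), 3 * sqrt(0.5 * ldr_kb))

  # ref alleles match the genome, ref != alt
  seqs <- setNames(g$scaffolds$sequence, g$scaffolds$scaffold)
  s1 <- sv$snvs[sv$snvs$lineage == "BR", ]
  expect_true(all(stringr::str_sub(seqs[s1$scaffold], s1$pos, s1$pos) == s1$ref))
  expect_true(all(s1$ref != s1$alt))

  # with zero background het rates, het calls only occur inside duplications
  p2 <- small_sim_params(seed = 23, het_snv_per_kb = c(island = 0, ldr = 0))
  sv2 <- simulate_snvs(simulate_genome(p2), p2)
  het_pos <- sv2$snvs[sv2$snvs$zygosity == "het", c("scaffold", "pos")]
  dups <- simulate_genome(p2)$truth$duplications
  in_dup <- vapply(seq_len(nrow(het_pos)), function(i) {
    any(dups$scaffold == het_pos$scaffold[i] &
          dups$start <= het_pos$pos[i] & dups$end >= het_pos$pos[i])
  }, logical(1))
  expect_true(all(in_dup))

  p0 <- small_sim_params(seed = 23, hom_snv_per_kb = c(island = 0, ldr = 0),
                         het_snv_per_kb = c(island = 0, ldr = 0),
                         n_duplications = 0L)
  sv0 <- simulate_snvs(simulate_genome(p0), p0)
  expect_equal(nrow(sv0$snvs), 0)
})

test_that("expression counts respect the island down-factor", {
  p <- small_sim_params(seed = 31)
  g <- simulate_genome(p)
  ex <- simulate_counts(g, p)
  med <- ex$counts |>
    dplyr::mutate(total = rowSums(dplyr::across(-gene_id))) |>
    dplyr::left_join(g$truth$genes[, c("gene_id", "region")], by = "gene_id") |>
    dplyr::group_by(region) |>
    dplyr::summarise(m = median(total))
  expect_lt(med$m[med$region == "island"], med$m[med$region == "ldr"] / 5)

  p1 <- small_sim_params(seed = 31, expr_island_down = 1,
                         expr_island_group_effect = 1)
  ex1 <- simulate_counts(g, p1)
  med1 <- ex1$counts |>
    dplyr::mutate(total = rowSums(dplyr::across(-gene_id))) |>
    dplyr::left_join(g$truth$genes[, c("gene_id", "region")], by = "gene_id") |>
    dplyr::group_by(region) |>
    dplyr::summarise(m = median(total))
  ratio <- med1$m[med1$region == "island"] / med1$m[med1$region == "ldr"]
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 3)

  # dispersion 0 falls back to Poisson and still runs deterministically
  p2 <- small_sim_params(seed = 31, expr_dispersion = 0)
  expect_identical(simulate_counts(g, p2)$counts,
                   simulate_counts(g, p2)$counts)
})

test_that("SNV substitution builds lineage consensus sequences", {
  scaff <- tibble::tibble(scaffold = "s1", length = 8L, sequence = "AAAAAAAA")
  s <- dplyr::bind_rows(
    snv_rows("s1", 5, "BR", "hom_alt", alt = "G"),
    snv_rows("s1", 2, "BR", "het", alt = "C"),
    snv_rows("s1", 7, "JP", "hom_alt", alt = "T")
  )
  out <- substitute_snvs(scaff, s, "BR")
  expect_equal(out$sequence, "AAAAGAAA")  # only the hom_alt position changes
  expect_equal(substitute_snvs(scaff, s[0, ], "BR")$sequence, "AAAAAAAA")
})

test_that("written dataset files parse back through the readers unchanged", {
  dir <- withr::local_tempdir()
  p <- small_sim_params(seed = 17)
  out <- simulate_dataset(p, dir)
  g <- out$genome

  sc <- read_genome_fasta(out$fasta)
  expect_equal(sc$sequence, g$scaffolds$sequence)

  f <- read_annotation_gff(out$gff)
  expect_equal(nrow(f), nrow(g$features))
  te_in <- g$features[g$features$kind == "te_copy", ]
  te_out <- f[f$kind == "te_copy", ]
  expect_equal(te_out$start, te_in$start)
  expect_equal(te_out$superfamily, te_in$superfamily)

  s <- read_snv_vcf(out$vcf, lineages = p$lineages)
  expect_equal(attr(s, "n_skipped"), 0)
  orig <- out$snv_sim$snvs |> dplyr::arrange(scaffold, pos, lineage)
  got <- s |> dplyr::arrange(scaffold, pos, lineage)
  expect_equal(got$zygosity, orig$zygosity)
  expect_equal(got$depth, orig$depth)

  d <- read_depth_tsv(out$depth[["BR"]], "BR")
  expect_equal(nrow(d), sum(g$scaffolds$length))
  expect_equal(d$depth[1:100], out$coverage$BR$depth[1:100])

  cnt <- read_count_tsv(out$counts)
  expect_equal(dim(cnt), dim(out$expr_sim$counts))

  truth_bed <- read_intervals_bed(out$truth_bed)
  expect_equal(truth_bed$start, g$truth$islands$start)
  expect_equal(truth_bed$end, g$truth$islands$end)
})
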