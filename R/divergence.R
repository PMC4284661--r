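#' Per-window between-lineage coverage ratios
#'
#' Averages read depth per fixed window in each lineage, masks windows with
#' mean depth below `min_depth` in either lineage (ratios at negligible
#' coverage are mapping artifacts, not signal), computes the coverage ratio
#' `r = depth_A / depth_B`, normalises by the genome-wide centre of the
#' unmasked ratios and reports the deviation `d = |r / centre - 1|`.
#'
#' @param depth_a,depth_b Depth tibbles (see [read_depth_tsv()]) for
#'   lineages A and B; the conventional orientation is A = BR, B = JP.
#' @param scaffold_lengths Named vector or scaffold/length data frame.
#' @param window Window width in bp (default 1000).
#' @param min_depth Mask threshold on mean window depth (default 5).
#' @param center `"median"` (default, robust to CNV outliers) or `"mean"`
#'   normalisation of the ratio.
#' @return A `coverage_ratio` tibble: `scaffold`, `start`, `end`,
#'   `depth_a`, `depth_b`, `masked`, `ratio`, `deviation` (`NA` when
#'   masked). The normalising centre is attached as attribute
#'   `center_ratio`.
#' @export
coverage_ratio_windows <- function(depth_a, depth_b, scaffold_lengths,
                                   window = 1000, min_depth = 5,
                                   center = c("median", "mean")) {
  center <- match.arg(center)
  sl <- as_scaffold_lengths(scaffold_lengths)
  ta <- tile_windows(NULL, sl, coverage = depth_a |> mutate(lineage = "a"),
                     window_size = window)
  tb <- tile_windows(NULL, sl, coverage = depth_b |> mutate(lineage = "b"),
                     window_size = window)
  out <- ta |>
    as_tibble() |>
    select("scaffold", "start", "end", depth_a = "depth_a") |>
    mutate(depth_b = tb$depth_b) |>
    mutate(
      masked = .data$depth_a < min_depth | .data$depth_b < min_depth,
      ratio = if_else(.data$masked, NA_real_, .data$depth_a / .data$depth_b)
    )
  if (all(out$masked)) abort("no unmasked windows: cannot normalise coverage ratio")
  ctr <- if (center == "median") {
    median(out$ratio[!out$masked])
  } else {
    mean(out$ratio[!out$masked])
  }
  out <- out |> mutate(deviation = abs(.data$ratio / ctr - 1))
  attr(out, "center_ratio") <- ctr
  class(out) <- c("coverage_ratio", class(out))
  out
}

#' Compare coverage-ratio deviations between islands and LDRs
#'
#' Windows are assigned to compartments by midpoint; the median deviation
#' is reported per compartment together with a two-sided Mann-Whitney test.
#'
#' @param ratio_windows Output of [coverage_ratio_windows()].
#' @param partition A `region_partition`.
#' @return A one-row tibble: `median_islands`, `median_ldr`, `n_islands`,
#'   `n_ldr`, `u`, `p_value`, `undefined_region` (`"island"`/`"ldr"` when a
#'   compartment had no unmasked windows, else `NA`).
#' @export
region_deviation_summary <- function(ratio_windows, partition) {
  w <- ratio_windows |>
    as_tibble() |>
    filter(!.data$masked) |>
    assign_region(partition)
  di <- w |> filter(.data$region == "island") |> pull("deviation")
  dl <- w |> filter(.data$region == "ldr") |> pull("deviation")
  undef <- if (length(di) == 0) "island" else if (length(dl) == 0) "ldr" else NA_character_
  test <- if (length(di) >= 1 && length(dl) >= 1) {
    mann_whitney_u(di, dl)
  } else {
    tibble(u = NA_real_, p_value = NA_real_)
  }
  tibble(
    median_islands = if (length(di)) median(di) else NA_real_,
    median_ldr = if (length(dl)) median(dl) else NA_real_,
    n_islands = length(di), n_ldr = length(dl),
    u = test$u, p_value = test$p_value,
    undefined_region = undef
  )
}

#' Classify heterozygous SNVs by relative coverage
#'
#' In pooled haploid data, true heterozygous calls should be rare; calls in
#' duplicated loci that were collapsed into one assembly locus show roughly
#' twofold coverage. A het call whose depth is at least `fold_threshold`
#' times the lineage's median depth (boundary inclusive) is labelled
#' `collapsed_duplication`, otherwise `true_het`. Homozygous calls are
#' labelled `hom`; zero-depth records are `masked`.
#'
#' @param snvs Long SNV tibble (see [read_snv_vcf()]).
#' @param lineage Which lineage's genotypes/depths to classify.
#' @param median_depth That lineage's genome-wide median depth (> 0).
#' @param fold_threshold Fold-coverage cutoff (default 1.5, the valley
#'   between the 1x and 2x coverage modes of het calls).
#' @return A tibble of that lineage's SNVs with added columns `fold`
#'   (depth / median depth) and `label`.
#' @export
classify_het_snvs <- function(snvs, lineage, median_depth,
                              fold_threshold = 1.5) {
  if (fold_threshold < 0) abort("fold_threshold must be non-negative")
  stopifnot(median_depth > 0)
  snvs |>
    filter(.data$lineage == !!lineage) |>
    mutate(
      fold = .data$depth / median_depth,
      label = dplyr::case_when(
        .data$depth == 0 ~ "masked",
        .data$zygosity %in% c("hom_ref", "hom_alt") ~ "hom",
        .data$zygosity == "het" & .data$fold >= fold_threshold ~ "collapsed_duplication",
        .data$zygosity == "het" ~ "true_het",
        TRUE ~ "masked"
      )
    )
}

#' Count SNVs per compartment, lineage and zygosity
#'
#' @param snvs Long SNV tibble.
#' @param partition A `region_partition`.
#' @return A list with `by_class`: per (lineage, zygosity) counts
#'   `n_islands`, `n_ldr`, `n_unassigned`, `n_total` and
#'   `pct_islands` (island share of assigned + unassigned total, in
#'   percent); and `overall`: one row with the island share of all SNV
#'   sites (`n_sites_islands`, `n_sites`, `pct_islands`).
#' @export
snv_region_summary <- function(snvs, partition) {
  s <- assign_region(snvs, partition)
  by_class <- s |>
    group_by(.data$lineage, .data$zygosity) |>
    summarise(
      n_islands = sum(.data$region == "island"),
      n_ldr = sum(.data$region == "ldr"),
      n_unassigned = sum(.data$region == "unassigned"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(pct_islands = 100 * .data$n_islands / .data$n_total)
  sites <- s |> distinct(.data$scaffold, .data$pos, .data$region)
  overall <- tibble(
    n_sites_islands = sum(sites$region == "island"),
    n_sites = nrow(sites),
    pct_islands = if (nrow(sites) > 0) 100 * sum(sites$region == "island") / nrow(sites) else NA_real_
  )
  list(by_class = by_class, overall = overall)
}

# --- coding-effect annotation -------------------------------------------

# Spliced CDS sequence of a gene in translation order (reverse-complemented
# for minus-strand genes) plus, for each genomic position in the CDS, its
# 1-based index in that sequence.
cds_layout <- function(gene, sequence) {
  cds <- gene$cds[[1]] |> arrange(.data$start)
  pieces <- stringr::str_sub(sequence, cds$start, cds$end)
  fwd <- paste(pieces, collapse = "")
  pos <- unlist(purrr::map2(cds$start, cds$end, seq), use.names = FALSE)
  if (identical(gene$strand, "-")) {
    seq_tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    idx <- rev(seq_along(pos))
  } else {
    seq_tx <- fwd
    idx <- seq_along(pos)
  }
  list(seq = seq_tx, pos = pos, idx = idx)
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Annotate the coding effect of SNVs
#'
#' Labels each SNV site `synonymous`, `nonsynonymous`, `noncoding` or
#' `unknown`. A site inside a complete CDS is translated in its codon
#' context (standard nuclear genetic code, reverse-complemented for
#' minus-strand genes) for the reference and alternate allele. Sites in
#' genes whose CDS length is not a multiple of 3, or whose codon contains
#' `N`, are `unknown`.
#'
#' @param snvs SNV tibble (unique sites are annotated; the long
#'   lineage-wise form is accepted and all rows of a site get the label).
#' @param genes Gene models from [gene_models()].
#' @param scaffolds Scaffold tibble from [read_genome_fasta()] (sequences
#'   required).
#' @return `snvs` with an `effect` column (and `gene_id` of the assigned
#'   CDS, `NA` for noncoding sites).
#' @export
annotate_snv_effect <- function(snvs, genes, scaffolds) {
  sites <- snvs |> distinct(.data$scaffold, .data$pos, .data$ref, .data$alt)
  sites$effect <- "noncoding"
  sites$gene_id <- NA_character_
  seqs <- setNames(scaffolds$sequence, scaffolds$scaffold)
  code <- Biostrings::GENETIC_CODE

  genes_cds <- genes |> filter(purrr::map_int(.data$cds, nrow) > 0)
  for (i in seq_len(nrow(genes_cds))) {
    g <- genes_cds[i, ]
    cds <- g$cds[[1]]
    on_g <- which(sites$scaffold == g$scaffold & sites$effect == "noncoding" &
                    sites$pos >= min(cds$start) & sites$pos <= max(cds$end))
    if (length(on_g) == 0) next
    in_cds <- on_g[purrr::map_lgl(sites$pos[on_g], function(p) {
      any(p >= cds$start & p <= cds$end)
    })]
    if (length(in_cds) == 0) next
    if (is.na(seqs[g$scaffold])) abort(sprintf("sequence absent for scaffold %s", g$scaffold))
    if (!g$cds_complete) {
      sites$effect[in_cds] <- "unknown"
      sites$gene_id[in_cds] <- g$gene_id
      next
    }
    lay <- cds_layout(g, seqs[[g$scaffold]])
    for (j in in_cds) {
      tx <- lay$idx[match(sites$pos[j], lay$pos)]
      ref_tx <- sites$ref[j]
      alt_tx <- sites$alt[j]
      if (identical(g$strand, "-")) {
        ref_tx <- complement_base[[ref_tx]]
        alt_tx <- complement_base[[alt_tx]]
      }
      codon_i <- (tx - 1) %/% 3
      cod <- stringr::str_sub(lay$seq, codon_i * 3 + 1, codon_i * 3 + 3)
      off <- tx - codon_i * 3
      if (stringr::str_sub(cod, off, off) != ref_tx) {
        # reference allele disagrees with the assembly sequence
        sites$effect[j] <- "unknown"
        sites$gene_id[j] <- g$gene_id
        next
      }
      cod_alt <- cod
      stringr::str_sub(cod_alt, off, off) <- alt_tx
      if (stringr::str_detect(paste0(cod, cod_alt), "N")) {
        sites$effect[j] <- "unknown"
      } else {
        sites$effect[j] <- if (code[[cod]] == code[[cod_alt]]) "synonymous" else "nonsynonymous"
      }
      sites$gene_id[j] <- g$gene_id
    }
  }
  snvs |>
    select(-any_of(c("effect", "gene_id"))) |>
    left_join(sites, by = c("scaffold", "pos", "ref", "alt"))
}

#' Per-gene dN/(dN+dS) and regional comparison
#'
#' Counts nonsynonymous (dN) and synonymous (dS) SNV sites per gene,
#' computes the fraction dN/(dN+dS) for genes with at least one coding SNV,
#' and compares island against LDR gene fractions with a two-sided
#' Mann-Whitney test. Also reports synonymous SNV sites per kb of CDS in
#' each compartment.
#'
#' @param snvs_annotated SNVs with `effect` and `gene_id` columns (see
#'   [annotate_snv_effect()]).
#' @param genes Gene models from [gene_models()].
#' @param partition A `region_partition`.
#' @return A list: `per_gene` tibble (`gene_id`, `region`, `dn`, `ds`,
#'   `fraction`), `comparison` one-row tibble (`median_islands`,
#'   `median_ldr`, `n_islands`, `n_ldr`, `u`, `p_value`) and `syn_per_kb`
#'   tibble per region (`region`, `syn_sites`, `cds_kb`, `syn_per_kb`).
#' @export
gene_dn_ds <- function(snvs_annotated, genes, partition) {
  sites <- snvs_annotated |>
    filter(!is.na(.data$gene_id),
           .data$effect %in% c("synonymous", "nonsynonymous")) |>
    distinct(.data$scaffold, .data$pos, .data$gene_id, .data$effect)
  per_gene <- genes |>
    select("gene_id", "scaffold", "start", "end") |>
    assign_region(partition) |>
    left_join(
      sites |>
        group_by(.data$gene_id) |>
        summarise(dn = sum(.data$effect == "nonsynonymous"),
                  ds = sum(.data$effect == "synonymous"), .groups = "drop"),
      by = "gene_id"
    ) |>
    mutate(
      dn = dplyr::coalesce(.data$dn, 0L),
      ds = dplyr::coalesce(.data$ds, 0L),
      fraction = if_else(.data$dn + .data$ds > 0,
                         .data$dn / (.data$dn + .data$ds), NA_real_)
    ) |>
    select("gene_id", "region", "dn", "ds", "fraction")

  fi <- per_gene |> filter(.data$region == "island", !is.na(.data$fraction)) |> pull("fraction")
  fl <- per_gene |> filter(.data$region == "ldr", !is.na(.data$fraction)) |> pull("fraction")
  comparison <- if (length(fi) >= 1 && length(fl) >= 1) {
    mw <- mann_whitney_u(fi, fl)
    tibble(median_islands = median(fi), median_ldr = median(fl),
           n_islands = length(fi), n_ldr = length(fl),
           u = mw$u, p_value = mw$p_value)
  } else {
    tibble(median_islands = if (length(fi)) median(fi) else NA_real_,
           median_ldr = if (length(fl)) median(fl) else NA_real_,
           n_islands = length(fi), n_ldr = length(fl),
           u = NA_real_, p_value = NA_real_)
  }

  cds_kb <- genes |>
    assign_region(partition) |>
    group_by(.data$region) |>
    summarise(cds_kb = sum(.data$cds_len) / 1000, .groups = "drop")
  syn <- per_gene |>
    group_by(.data$region) |>
    summarise(syn_sites = sum(.data$ds), .groups = "drop") |>
    left_join(cds_kb, by = "region") |>
    mutate(syn_per_kb = if_else(.data$cds_kb > 0,
                                .data$syn_sites / .data$cds_kb, NA_real_))
  list(per_gene = per_gene, comparison = comparison, syn_per_kb = syn)
}

#' Flag copy-number-variant candidate loci
#'
#' Unmasked 1 kb ratio windows whose normalised deviation reaches
#' `deviation_threshold` are merged when adjacent, annotated with
#' overlapping gene ids and compartment, and returned ranked by peak
#' deviation.
#'
#' @param ratio_windows Output of [coverage_ratio_windows()] at 1 kb.
#' @param genes Gene tibble with `gene_id`, `scaffold`, `start`, `end`.
#' @param partition A `region_partition`.
#' @param deviation_threshold Minimum deviation to flag (default 0.5).
#' @return A tibble of candidate loci: `scaffold`, `start`, `end`,
#'   `max_deviation`, `region`, `genes` (comma-separated overlapping gene
#'   ids), sorted by decreasing `max_deviation`.
#' @export
flag_cnv_candidates <- function(ratio_windows, genes, partition,
                                deviation_threshold = 0.5) {
  hits <- ratio_windows |>
    as_tibble() |>
    filter(!.data$masked, .data$deviation >= deviation_threshold)
  if (nrow(hits) == 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  max_deviation = numeric(), region = character(),
                  genes = character()))
  }
  merged <- hits |>
    group_by(.data$scaffold) |>
    dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
    ungroup()
  merged$max_deviation <- purrr::pmap_dbl(
    list(merged$scaffold, merged$start, merged$end),
    function(sc, s, e) {
      max(hits$deviation[hits$scaffold == sc & hits$start >= s & hits$end <= e])
    }
  )
  merged$genes <- purrr::pmap_chr(
    list(merged$scaffold, merged$start, merged$end),
    function(sc, s, e) {
      g <- genes |> filter(.data$scaffold == sc, .data$start <= e, .data$end >= s)
      paste(g$gene_id, collapse = ",")
    }
  )
  merged |>
    assign_region(partition) |>
    select("scaffold", "start", "end", "max_deviation", "region", "genes") |>
    arrange(dplyr::desc(.data$max_deviation))
}
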