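#' Observed/expected CpG ratio of a sequence
#'
#' `o/e = n_CpG * L / (n_C * n_G)` with an overlapping dinucleotide scan.
#' `N` bases are excluded from the mononucleotide counts and from `L`, and
#' a CpG interrupted by `N` is not counted. Undefined (NA) when the
#' sequence is shorter than 2 informative bases or contains no C or no G.
#'
#' @param sequence Character vector of A/C/G/T/N strings (vectorised).
#' @return Numeric vector of o/e values (`NA` where undefined).
#' @examples
#' cpg_oe("ACGT")     # 4
#' cpg_oe("CGCGCG")   # 2
#' @export
cpg_oe <- function(sequence) {
  counts <- cpg_counts(sequence)
  with(counts, if_else(len >= 2 & c_count > 0 & g_count > 0,
                       cpg * len / (c_count * g_count), NA_real_))
}

# Vectorised raw counts behind cpg_oe / gene profiles.
cpg_counts <- function(sequence) {
  sequence <- toupper(sequence)
  tibble(
    cpg = stringr::str_count(sequence, "CG"),
    c_count = stringr::str_count(sequence, "C"),
    g_count = stringr::str_count(sequence, "G"),
    len = stringr::str_count(sequence, "[ACGT]")
  )
}

#' Exon-wide CpG profile of genes
#'
#' Counts are taken per exon and summed, so CpG pairs spanning an exon
#' junction are not counted; the o/e ratio is computed on the summed
#' counts. This makes the profile independent of exon order.
#'
#' @param genes Gene models from [gene_models()] (the `exons` list column
#'   is used; genes without exons get `NA`).
#' @param scaffolds Scaffold tibble from [read_genome_fasta()] with
#'   sequences.
#' @return A tibble: `gene_id`, `cpg_count`, `c_count`, `g_count`, `length`
#'   (informative bases), `oe`.
#' @export
gene_exon_cpg_oe <- function(genes, scaffolds) {
  seqs <- setNames(scaffolds$sequence, scaffolds$scaffold)
  if (any(is.na(seqs[unique(genes$scaffold)]))) {
    abort("sequence absent for one or more gene scaffolds")
  }
  prof <- purrr::map2(genes$exons, genes$scaffold, function(ex, sc) {
    if (nrow(ex) == 0) {
      return(tibble(cpg = NA_integer_, c_count = NA_integer_,
                    g_count = NA_integer_, len = NA_integer_))
    }
    pieces <- stringr::str_sub(seqs[[sc]], ex$start, ex$end)
    cpg_counts(pieces) |>
      summarise(across(dplyr::everything(), sum))
  }) |> bind_rows()
  tibble(
    gene_id = genes$gene_id,
    cpg_count = prof$cpg,
    c_count = prof$c_count,
    g_count = prof$g_count,
    length = prof$len,
    oe = if_else(prof$len >= 2 & prof$c_count > 0 & prof$g_count > 0,
                 prof$cpg * prof$len / (prof$c_count * prof$g_count),
                 NA_real_)
  )
}

#' Between-lineage CpG o/e ratio variance test
#'
#' Computes per-unit ratios `oe_A / oe_B` of matched CpG o/e values from
#' two lineage consensus sequence sets and tests whether the ratios are
#' more variable in islands than in LDRs: `F = var(island) / var(LDR)`,
#' two-sided p from the F distribution with `(n_isl - 1, n_ldr - 1)` df.
#'
#' @param profiles_a,profiles_b Tibbles with `gene_id` and `oe` (same units
#'   in both, e.g. [gene_exon_cpg_oe()] on two lineage genomes).
#' @param regions Tibble mapping `gene_id` to `region` (`island`/`ldr`),
#'   e.g. from [assign_region()].
#' @return A one-row tibble: `f`, `df_islands`, `df_ldr`, `p_value`,
#'   `var_islands`, `var_ldr`, `n_islands`, `n_ldr`, `degenerate` (`TRUE`
#'   when either variance is 0).
#' @export
lineage_oe_ratio_test <- function(profiles_a, profiles_b, regions) {
  m <- profiles_a |>
    select("gene_id", oe_a = "oe") |>
    dplyr::inner_join(profiles_b |> select("gene_id", oe_b = "oe"),
                      by = "gene_id") |>
    filter(!is.na(.data$oe_a), !is.na(.data$oe_b),
           .data$oe_a > 0, .data$oe_b > 0) |>
    mutate(ratio = .data$oe_a / .data$oe_b) |>
    dplyr::inner_join(regions |> select("gene_id", "region"), by = "gene_id")
  ri <- m |> filter(.data$region == "island") |> pull("ratio")
  rl <- m |> filter(.data$region == "ldr") |> pull("ratio")
  if (length(ri) < 2 || length(rl) < 2) {
    abort("need at least 2 ratios in each compartment for the variance test")
  }
  vi <- stats::var(ri)
  vl <- stats::var(rl)
  degenerate <- vi == 0 || vl == 0
  f <- if (vl > 0) vi / vl else NA_real_
  p <- if (!degenerate) {
    pf <- stats::pf(f, length(ri) - 1, length(rl) - 1)
    min(1, 2 * min(pf, 1 - pf))
  } else {
    NA_real_
  }
  tibble(f = f, df_islands = length(ri) - 1, df_ldr = length(rl) - 1,
         p_value = p, var_islands = vi, var_ldr = vl,
         n_islands = length(ri), n_ldr = length(rl), degenerate = degenerate)
}
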