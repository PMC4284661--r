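#' Tally TE copies and bases per superfamily and region
#'
#' Each TE copy is assigned to the compartment containing its midpoint;
#' its bases are split exactly at island boundaries, so per-superfamily bp
#' sums are additive across regions. Copies without a superfamily attribute
#' are tallied as `"unclassified"`.
#'
#' @param features Annotation tibble; rows of kind `te_copy` are used.
#' @param partition A `region_partition`.
#' @return A tibble with one row per superfamily: `superfamily`,
#'   `te_class`, `copies_islands`, `copies_ldr`, `bp_islands`, `bp_ldr`.
#'   Copies on non-eligible scaffolds count as LDR-side background.
#' @export
tally_superfamilies <- function(features, partition) {
  te <- features |>
    filter(.data$kind == "te_copy") |>
    mutate(superfamily = dplyr::coalesce(.data$superfamily, "unclassified"))
  if (nrow(te) == 0) {
    return(tibble(superfamily = character(), te_class = character(),
                  copies_islands = integer(), copies_ldr = integer(),
                  bp_islands = numeric(), bp_ldr = numeric()))
  }
  te <- assign_region(te, partition)
  isl <- partition$islands
  bp_in_islands <- numeric(nrow(te))
  for (sc in unique(isl$scaffold)) {
    idx <- which(te$scaffold == sc)
    if (length(idx) == 0) next
    is_sc <- isl |> filter(.data$scaffold == sc)
    bp_in_islands[idx] <- overlap_bp(te$start[idx], te$end[idx],
                                     is_sc$start, is_sc$end)
  }
  te |>
    mutate(
      len = .data$end - .data$start + 1,
      bp_isl = bp_in_islands,
      in_island = .data$region == "island"
    ) |>
    group_by(.data$superfamily) |>
    summarise(
      te_class = dplyr::first(.data$te_class[!is.na(.data$te_class)], default = NA_character_),
      copies_islands = sum(.data$in_island),
      copies_ldr = sum(!.data$in_island),
      bp_islands = sum(.data$bp_isl),
      bp_ldr = sum(.data$len - .data$bp_isl),
      .groups = "drop"
    )
}

enrichment_table <- function(tallies, isl_col, ldr_col, alpha) {
  a_all <- tallies[[isl_col]]
  b_all <- tallies[[ldr_col]]
  res <- purrr::map(seq_len(nrow(tallies)), function(i) {
    tab <- matrix(c(a_all[i], b_all[i],
                    sum(a_all[-i]), sum(b_all[-i])), 2, 2, byrow = TRUE)
    ft <- fisher_exact_two_sided(tab)
    tibble(
      unit = tallies$superfamily[i],
      a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  }) |> bind_rows()
  res |>
    mutate(
      q_value = bh_fdr(.data$p_value),
      direction = if_else(is.na(.data$odds_ratio) | .data$odds_ratio >= 1,
                          "over", "under"),
      significant = !is.na(.data$q_value) & .data$q_value < alpha
    )
}

#' Test repeat superfamilies for island enrichment
#'
#' For each superfamily, a 2x2 table of island/LDR counts against all other
#' superfamilies combined is tested with the two-sided Fisher exact test;
#' q-values are Benjamini-Hochberg across superfamilies. The same machinery
#' is run twice: once on copy numbers and once on base counts.
#'
#' @param tallies Output of [tally_superfamilies()] (at least two
#'   superfamilies required).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return A `te_enrichment` tibble with one row per superfamily per
#'   analysis: `analysis` (`copies` or `bp`), `unit`, the 2x2 cells
#'   `a`,`b`,`c`,`d`, `odds_ratio`, `p_value`, `q_value`, `direction`
#'   (`over`/`under` island representation), `significant`. A single
#'   superfamily is degenerate: empty result with a warning.
#' @export
superfamily_enrichment <- function(tallies, alpha = 0.05) {
  cols <- c("analysis", "unit", "a", "b", "c", "d", "odds_ratio",
            "p_value", "q_value", "direction", "significant")
  if (nrow(tallies) < 2) {
    warn("fewer than 2 superfamilies: enrichment comparison is degenerate")
    out <- tibble(analysis = character(), unit = character(),
                  a = numeric(), b = numeric(), c = numeric(), d = numeric(),
                  odds_ratio = numeric(), p_value = numeric(),
                  q_value = numeric(), direction = character(),
                  significant = logical())
    class(out) <- c("te_enrichment", class(out))
    return(out)
  }
  out <- bind_rows(
    enrichment_table(tallies, "copies_islands", "copies_ldr", alpha) |>
      mutate(analysis = "copies"),
    enrichment_table(tallies |> mutate(bp_islands = round(.data$bp_islands),
                                       bp_ldr = round(.data$bp_ldr)),
                     "bp_islands", "bp_ldr", alpha) |>
      mutate(analysis = "bp")
  ) |> select(all_of(cols))
  class(out) <- c("te_enrichment", class(out))
  out
}

#' Compare TE copy lengths between islands and LDRs
#'
#' Per TE class (I, II), copy lengths (end - start + 1, midpoint region
#' assignment) in islands are compared with LDR lengths by a two-sided
#' Mann-Whitney U test.
#'
#' @param features Annotation tibble with `te_copy` rows carrying
#'   `te_class`.
#' @param partition A `region_partition`.
#' @return A tibble with one row per TE class: `te_class`, `n_islands`,
#'   `n_ldr`, `median_islands`, `median_ldr`, `u`, `p_value`, `skipped`
#'   (`TRUE` when a region has fewer than 2 copies and the test cannot
#'   run).
#' @export
length_polymorphism <- function(features, partition) {
  te <- features |>
    filter(.data$kind == "te_copy", !is.na(.data$te_class)) |>
    assign_region(partition) |>
    mutate(len = .data$end - .data$start + 1)
  purrr::map(sort(unique(te$te_class)), function(cl) {
    x <- te |> filter(.data$te_class == cl, .data$region == "island") |> pull("len")
    y <- te |> filter(.data$te_class == cl, .data$region != "island") |> pull("len")
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(te_class = cl, n_islands = length(x), n_ldr = length(y),
                    median_islands = median(x), median_ldr = median(y),
                    u = NA_real_, p_value = NA_real_, skipped = TRUE))
    }
    mw <- mann_whitney_u(x, y)
    tibble(te_class = cl, n_islands = length(x), n_ldr = length(y),
           median_islands = median(x), median_ldr = median(y),
           u = mw$u, p_value = mw$p_value, skipped = FALSE)
  }) |> bind_rows()
}

#' Two-tailed term enrichment for island genes
#'
#' For each term, island genes with/without the term are compared against
#' non-island universe genes with a two-sided Fisher exact test;
#' Benjamini-Hochberg across terms. Both over- and under-represented terms
#' are reported (the `direction` column), which is what a two-tailed
#' enrichment screen means here.
#'
#' @param gene_terms Tibble with columns `gene_id`, `term`.
#' @param island_genes Character vector of island gene ids (must be a
#'   subset of `universe`).
#' @param universe Character vector of all gene ids under consideration.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return A `te_enrichment` tibble, one row per term, same columns as
#'   [superfamily_enrichment()] with `analysis = "terms"`. Terms with no
#'   gene in the universe are skipped.
#' @export
term_enrichment_two_tailed <- function(gene_terms, island_genes, universe,
                                       alpha = 0.05) {
  stopifnot(all(island_genes %in% universe))
  universe <- unique(universe)
  island_genes <- unique(island_genes)
  n_isl <- length(island_genes)
  n_out <- length(universe) - n_isl
  gt <- gene_terms |> filter(.data$gene_id %in% universe) |> distinct()
  cols <- c("analysis", "unit", "a", "b", "c", "d", "odds_ratio",
            "p_value", "q_value", "direction", "significant")
  if (nrow(gt) == 0) {
    out <- tibble(analysis = character(), unit = character(), a = numeric(),
                  b = numeric(), c = numeric(), d = numeric(),
                  odds_ratio = numeric(), p_value = numeric(),
                  q_value = numeric(), direction = character(),
                  significant = logical())
    class(out) <- c("te_enrichment", class(out))
    return(out)
  }
  res <- gt |>
    group_by(term = .data$term) |>
    summarise(
      a = sum(.data$gene_id %in% island_genes),
      c = dplyr::n() - sum(.data$gene_id %in% island_genes),
      .groups = "drop"
    ) |>
    mutate(b = n_isl - .data$a, d = n_out - .data$c)
  tests <- purrr::pmap(list(res$a, res$b, res$c, res$d), function(a, b, c, d) {
    fisher_exact_two_sided(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))
  }) |> bind_rows()
  out <- res |>
    mutate(
      analysis = "terms",
      unit = .data$term,
      odds_ratio = tests$odds_ratio,
      p_value = tests$p_value,
      q_value = bh_fdr(tests$p_value),
      direction = if_else(is.na(.data$odds_ratio) | .data$odds_ratio >= 1,
                          "over", "under"),
      significant = !is.na(.data$q_value) & .data$q_value < alpha
    ) |>
    select(all_of(cols))
  class(out) <- c("te_enrichment", class(out))
  out
}
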