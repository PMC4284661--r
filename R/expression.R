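#' Median-of-ratios size factors
#'
#' The classic library-size normalisation for count tables: the reference
#' for each gene is its geometric mean across samples (genes with any zero
#' count are excluded from the reference set), and each sample's factor is
#' the median across genes of count / reference.
#'
#' @param counts Count tibble with a `gene_id` column followed by one
#'   numeric column per sample (see [read_count_tsv()]), or a numeric
#'   matrix with gene rownames.
#' @return A named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  mat <- count_matrix(counts)
  log_mat <- log(mat)
  ok <- apply(is.finite(log_mat), 1, all)
  if (!any(ok)) abort("no gene has nonzero counts in every sample")
  log_ref <- rowMeans(log_mat[ok, , drop = FALSE])
  apply(log_mat[ok, , drop = FALSE], 2, function(cnt) {
    exp(median(cnt - log_ref))
  })
}

count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot("gene_id" %in% names(counts))
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(mat) <- counts$gene_id
  mat
}

#' Per-group mean normalised expression and expression ranks
#'
#' Divides counts by the sample size factors, averages per treatment group
#' and ranks genes by total normalised expression. The rank percentile runs
#' from 0 (least expressed) to 100 (most expressed) and is defined only
#' over genes with nonzero total normalised count; fully unexpressed genes
#' get `NA` and `expressed = FALSE`.
#'
#' @param counts Count tibble or matrix (see [size_factors()]).
#' @param groups Named character vector mapping sample id to group label
#'   (e.g. `c(q1 = "queen", l1 = "larva")`); every sample column must be
#'   mapped.
#' @return A tibble: `gene_id`, one `mean_<group>` column per group,
#'   `base_mean` (mean over all samples), `expressed`, `rank_percentile`.
#' @export
mean_normalized_expression <- function(counts, groups) {
  mat <- count_matrix(counts)
  missing_smp <- setdiff(colnames(mat), names(groups))
  if (length(missing_smp) > 0) {
    abort(sprintf("sample(s) without a group label: %s",
                  paste(missing_smp, collapse = ", ")))
  }
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  out <- tibble(gene_id = rownames(mat))
  for (g in unique(groups[colnames(mat)])) {
    smp <- colnames(mat)[groups[colnames(mat)] == g]
    out[[paste0("mean_", g)]] <- rowMeans(norm[, smp, drop = FALSE])
  }
  out$base_mean <- rowMeans(norm)
  total <- rowSums(norm)
  out$expressed <- total > 0
  out$rank_percentile <- NA_real_
  n_expr <- sum(out$expressed)
  if (n_expr == 1) {
    out$rank_percentile[out$expressed] <- 0
  } else if (n_expr > 1) {
    r <- rank(total[out$expressed], ties.method = "average")
    out$rank_percentile[out$expressed] <- (r - 1) / (n_expr - 1) * 100
  }
  out
}

#' Median CpG o/e along the expression rank
#'
#' Buckets expressed genes into `bins` equal-width rank-percentile bins and
#' reports the median gene CpG o/e per bin, separately for island and LDR
#' genes.
#'
#' @param summaries Output of [mean_normalized_expression()].
#' @param profiles Output of [gene_exon_cpg_oe()] (columns `gene_id`,
#'   `oe`).
#' @param regions Tibble mapping `gene_id` to `region`.
#' @param bins Number of rank bins (default 100).
#' @return A `rank_curve` tibble: `region`, `bin` (1-based), `rank_mid`
#'   (bin midpoint percentile), `n`, `median_oe`.
#' @export
expression_rank_curve <- function(summaries, profiles, regions, bins = 100) {
  m <- summaries |>
    filter(.data$expressed) |>
    select("gene_id", "rank_percentile") |>
    dplyr::inner_join(profiles |> select("gene_id", "oe"), by = "gene_id") |>
    dplyr::inner_join(regions |> select("gene_id", "region"), by = "gene_id") |>
    filter(!is.na(.data$oe))
  if (nrow(m) == 0) abort("no genes shared between expression summaries and CpG profiles")
  out <- m |>
    mutate(bin = pmin(bins, floor(.data$rank_percentile / 100 * bins) + 1L)) |>
    group_by(.data$region, .data$bin) |>
    summarise(n = dplyr::n(), median_oe = median(.data$oe), .groups = "drop") |>
    mutate(rank_mid = (.data$bin - 0.5) / bins * 100) |>
    select("region", "bin", "rank_mid", "n", "median_oe") |>
    arrange(.data$region, .data$bin)
  class(out) <- c("rank_curve", class(out))
  out
}

#' Compare expression between compartments and groups
#'
#' Median normalised expression per compartment per group (zeros included),
#' island-vs-LDR Mann-Whitney tests within each group and on the overall
#' base mean, a group-vs-group test within each compartment, and counts of
#' fully unexpressed genes per compartment.
#'
#' @param summaries Output of [mean_normalized_expression()].
#' @param regions Tibble mapping `gene_id` to `region`.
#' @param group_pair Length-2 character vector naming the two groups to
#'   contrast (their `mean_<group>` columns must exist).
#' @return A list of tibbles: `medians` (`region`, `group`, `median`, `n`),
#'   `island_vs_ldr` (per group + `base_mean`: medians, `u`, `p_value`),
#'   `group_vs_group` (per region: medians, `u`, `p_value`) and
#'   `unexpressed` (`region`, `n_unexpressed`, `n_genes`).
#' @export
compare_region_expression <- function(summaries, regions, group_pair) {
  cols <- paste0("mean_", group_pair)
  missing_cols <- setdiff(cols, names(summaries))
  if (length(missing_cols) > 0) {
    abort(sprintf("unknown group label(s): %s",
                  paste(sub("^mean_", "", missing_cols), collapse = ", ")))
  }
  m <- summaries |>
    dplyr::inner_join(regions |> select("gene_id", "region"), by = "gene_id") |>
    filter(.data$region %in% c("island", "ldr"))

  medians <- purrr::map(c(group_pair, "base_mean"), function(g) {
    col <- if (g == "base_mean") "base_mean" else paste0("mean_", g)
    m |>
      group_by(.data$region) |>
      summarise(group = g, median = median(.data[[col]]), n = dplyr::n(),
                .groups = "drop")
  }) |> bind_rows() |> select("region", "group", "median", "n")

  test_pair <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) {
      return(tibble(u = NA_real_, p_value = NA_real_))
    }
    mann_whitney_u(x, y) |> select("u", "p_value")
  }
  island_vs_ldr <- purrr::map(c(group_pair, "base_mean"), function(g) {
    col <- if (g == "base_mean") "base_mean" else paste0("mean_", g)
    xi <- m |> filter(.data$region == "island") |> pull(col)
    xl <- m |> filter(.data$region == "ldr") |> pull(col)
    bind_cols(tibble(group = g,
                     median_islands = if (length(xi)) median(xi) else NA_real_,
                     median_ldr = if (length(xl)) median(xl) else NA_real_),
              test_pair(xi, xl))
  }) |> bind_rows()

  group_vs_group <- purrr::map(c("island", "ldr"), function(rg) {
    x1 <- m |> filter(.data$region == rg) |> pull(cols[1])
    x2 <- m |> filter(.data$region == rg) |> pull(cols[2])
    bind_cols(tibble(region = rg,
                     median_1 = if (length(x1)) median(x1) else NA_real_,
                     median_2 = if (length(x2)) median(x2) else NA_real_),
              test_pair(x1, x2)) |>
      rename(!!paste0("median_", group_pair[1]) := "median_1",
             !!paste0("median_", group_pair[2]) := "median_2")
  }) |> bind_rows()

  unexpressed <- m |>
    group_by(.data$region) |>
    summarise(n_unexpressed = sum(!.data$expressed), n_genes = dplyr::n(),
              .groups = "drop")

  list(medians = medians, island_vs_ldr = island_vs_ldr,
       group_vs_group = group_vs_group, unexpressed = unexpressed)
}
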