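#' Planted-structure recovery study over simulation seeds
#'
#' For each seed, simulates a genome, coverage, SNVs and expression under
#' the given parameter settings, runs the full in-memory analysis (window
#' tracks, island calling, coverage-ratio deviations, het-SNV
#' classification, CpG profiles, size-factor-normalised expression) and
#' scores recovery of the planted structure.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param ... Overrides passed to [sim_params()] (the defaults are the
#'   standard study conditions).
#' @return A tibble with one row per seed: `seed`, `jaccard` (called vs
#'   planted islands), `dup_recall` and `n_dup_snvs`
#'   (collapsed-duplication classification), `dev_island`/`dev_ldr`
#'   (median coverage-ratio deviation), `snv_island_per_kb`/`snv_ldr_per_kb`
#'   (SNV site density), `te_len_island`/`te_len_ldr` (median copy length),
#'   `cpg_island`/`cpg_ldr` (median gene CpG o/e) and
#'   `expr_island`/`expr_ldr` (median normalised expression), all measured
#'   against the *called* partition.
#' @export
recovery_study <- function(seeds, ...) {
  purrr::map(seeds, function(seed) {
    p <- sim_params(seed = seed, ...)
    g <- simulate_genome(p)
    cov <- simulate_coverage(g, p)
    sv <- simulate_snvs(g, p, coverage = cov)
    ex <- simulate_counts(g, p)
    sl <- setNames(g$scaffolds$length, g$scaffolds$scaffold)

    tr1 <- tile_windows(g$features, sl, snvs = sv$snvs)
    part <- call_te_islands(aggregate_windows(tr1), tr1, sl)
    jac <- jaccard_intervals(g$truth$islands, part$islands)

    cls <- purrr::map(p$lineages, function(l) {
      dp <- sv$snvs$depth[sv$snvs$lineage == l]
      classify_het_snvs(sv$snvs, l, median(dp[dp > 0]),
                        fold_threshold = 1.5)
    }) |> bind_rows()
    planted <- cls |>
      dplyr::inner_join(sv$truth, by = c("scaffold", "pos")) |>
      filter(.data$true_class == "collapsed_duplication",
             .data$zygosity == "het")
    recall <- if (nrow(planted) > 0) {
      mean(planted$label == "collapsed_duplication")
    } else {
      NA_real_
    }

    rw <- coverage_ratio_windows(cov[[p$lineages[1]]], cov[[p$lineages[2]]], sl)
    dev <- region_deviation_summary(rw, part)

    ss <- snv_region_summary(sv$snvs, part)
    isl_kb <- sum(part$islands$end - part$islands$start + 1) / 1000
    ldr_kb <- sum(part$ldr$end - part$ldr$start + 1) / 1000
    n_isl <- ss$overall$n_sites_islands
    n_ldr <- ss$overall$n_sites - n_isl

    te <- assign_region(g$features |> filter(.data$kind == "te_copy"), part)
    te_len <- te |>
      mutate(len = .data$end - .data$start + 1) |>
      group_by(.data$region) |>
      summarise(m = median(.data$len), .groups = "drop")

    gm <- gene_models(g$features)
    prof <- gene_exon_cpg_oe(gm, g$scaffolds)
    gr <- gm |>
      select("gene_id", "scaffold", "start", "end") |>
      assign_region(part) |>
      select("gene_id", "region")
    cpg <- prof |>
      dplyr::inner_join(gr, by = "gene_id") |>
      filter(!is.na(.data$oe)) |>
      group_by(.data$region) |>
      summarise(m = median(.data$oe), .groups = "drop")

    summ <- mean_normalized_expression(ex$counts, ex$groups)
    expr <- summ |>
      dplyr::inner_join(gr, by = "gene_id") |>
      group_by(.data$region) |>
      summarise(m = median(.data$base_mean), .groups = "drop")

    pick <- function(df, rg) {
      v <- df$m[df$region == rg]
      if (length(v) == 0) NA_real_ else v
    }
    tibble(
      seed = seed,
      jaccard = jac,
      dup_recall = recall,
      n_dup_snvs = nrow(planted),
      dev_island = dev$median_islands,
      dev_ldr = dev$median_ldr,
      snv_island_per_kb = n_isl / isl_kb,
      snv_ldr_per_kb = n_ldr / ldr_kb,
      te_len_island = pick(te_len, "island"),
      te_len_ldr = pick(te_len, "ldr"),
      cpg_island = pick(cpg, "island"),
      cpg_ldr = pick(cpg, "ldr"),
      expr_island = pick(expr, "island"),
      expr_ldr = pick(expr, "ldr")
    )
  }) |> bind_rows()
}
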