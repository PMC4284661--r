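#' Jaccard index between two interval sets
#'
#' Intersection over union of total bp, computed per scaffold with both
#' sets union-merged first. Used to score recovery of planted islands.
#'
#' @param a,b Tibbles with `scaffold`, `start`, `end` (1-based inclusive).
#' @return A single number in `[0, 1]` (1 when both sets are empty).
#' @export
jaccard_intervals <- function(a, b) {
  scs <- union(unique(a$scaffold), unique(b$scaffold))
  inter <- 0
  uni <- 0
  for (sc in scs) {
    ia <- a |> filter(.data$scaffold == sc)
    ib <- b |> filter(.data$scaffold == sc)
    ra <- IRanges::reduce(IRanges::IRanges(ia$start, ia$end))
    rb <- IRanges::reduce(IRanges::IRanges(ib$start, ib$end))
    inter <- inter + sum(BiocGenerics::width(IRanges::intersect(ra, rb)))
    uni <- uni + sum(BiocGenerics::width(IRanges::union(ra, rb)))
  }
  if (uni == 0) 1 else inter / uni
}

default_pipeline_params <- function() {
  list(
    window_size = 1000, span = 200000, step = 1000,
    quantile = 0.95, min_scaffold = 200000, min_island = 10000,
    min_depth = 5, fold_threshold = 1.5, deviation_threshold = 0.5,
    alpha = 0.05, bins = 100, ratio_center = "median",
    lineages = c("BR", "JP"), groups = c("queen", "larva")
  )
}

validate_config <- function(config) {
  p <- default_pipeline_params()
  p[names(config$params %||% list())] <- config$params
  stopifnot(is.list(config))
  if (p$quantile < 0 || p$quantile > 1) abort("quantile must lie in [0, 1]")
  if (p$window_size < 1) abort("window_size must be >= 1")
  if (p$span %% p$window_size != 0) abort("span must be a multiple of window_size")
  if (p$min_depth < 0 || p$fold_threshold < 0 || p$deviation_threshold < 0) {
    abort("thresholds must be non-negative")
  }
  if (p$alpha <= 0 || p$alpha > 1) abort("alpha must lie in (0, 1]")
  required <- c("fasta", "gff")
  missing_in <- setdiff(required, names(config$inputs %||% list()))
  if (length(missing_in) > 0) {
    abort(sprintf("config lacks required input(s): %s",
                  paste(missing_in, collapse = ", ")))
  }
  config$params <- p
  config
}

#' Run the full TE-island analysis from a single config
#'
#' Executes the stages in dependency order: window tracks, island calling,
#' between-lineage divergence, composition statistics, CpG and expression.
#' Stages whose optional inputs (VCF, depth, counts, terms) are absent are
#' skipped and recorded in the report. Results are written as JSON + TSV +
#' BED into `out_dir` and returned.
#'
#' @param config A list (or path to a YAML file) with elements `inputs`
#'   (paths: `fasta`, `gff` required; `vcf`, `depth` (named per lineage),
#'   `counts`, `groups`, `terms` optional) and `params` (any of
#'   `window_size`, `span`, `step`, `quantile`, `min_scaffold`,
#'   `min_island`, `min_depth`, `fold_threshold`, `deviation_threshold`,
#'   `alpha`, `bins`, `ratio_center`, `lineages`, `groups`).
#' @param out_dir Output directory (created if needed).
#' @return The analysis report, a named list mirroring the written
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  p <- config$params
  inp <- config$inputs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  scaffolds <- stage("read_fasta", read_genome_fasta(inp$fasta))
  features <- stage("read_gff", read_annotation_gff(inp$gff))
  sl <- setNames(scaffolds$length, scaffolds$scaffold)
  genes <- gene_models(features)

  snvs <- NULL
  if (!is.null(inp$vcf)) {
    snvs <- stage("read_vcf", read_snv_vcf(inp$vcf, lineages = p$lineages))
  } else {
    skipped <- c(skipped, "snv")
  }
  depth <- NULL
  if (!is.null(inp$depth) && length(inp$depth) == 2) {
    depth <- stage("read_depth", purrr::imap(
      as.list(inp$depth), function(path, l) read_depth_tsv(path, l)
    ))
  } else {
    skipped <- c(skipped, "coverage")
  }

  track1 <- stage("windows", tile_windows(
    features, sl, snvs = snvs, window_size = p$window_size
  ))
  track200 <- aggregate_windows(track1, span = p$span, step = p$step)
  partition <- stage("islands", call_te_islands(
    track200, track1, sl, quantile = p$quantile,
    min_scaffold = p$min_scaffold, min_island = p$min_island
  ))
  report <- list(
    provenance = list(params = p, inputs = inp,
                      package_version = as.character(utils::packageVersion("teislandr")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    island_summary = island_summary(
      partition, features, features |> filter(.data$kind == "gene"),
      assembly_len = sum(scaffolds$length)
    ),
    islands = partition$islands
  )

  if (!is.null(depth)) {
    ratio <- stage("coverage_ratio", coverage_ratio_windows(
      depth[[p$lineages[1]]], depth[[p$lineages[2]]], sl,
      window = p$window_size, min_depth = p$min_depth,
      center = p$ratio_center
    ))
    report$region_deviation <- region_deviation_summary(ratio, partition)
    cnv <- flag_cnv_candidates(
      ratio, genes |> select("gene_id", "scaffold", "start", "end"),
      partition, deviation_threshold = p$deviation_threshold
    )
    report$n_cnv_candidates <- nrow(cnv)
    readr::write_tsv(cnv, file.path(out_dir, "cnv_candidates.tsv"),
                     progress = FALSE)
  } else {
    report$region_deviation <- "skipped"
  }

  if (!is.null(snvs)) {
    report$snv_summary <- snv_region_summary(snvs, partition)
    med_depth <- snvs |>
      group_by(.data$lineage) |>
      summarise(median_depth = median(.data$depth[.data$depth > 0]),
                .groups = "drop")
    cls <- purrr::map(p$lineages, function(l) {
      classify_het_snvs(snvs, l,
                        med_depth$median_depth[med_depth$lineage == l],
                        fold_threshold = p$fold_threshold)
    }) |> bind_rows()
    report$het_classification <- cls |>
      count(.data$lineage, .data$label) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n",
                         values_fill = 0L)
    readr::write_tsv(cls |> select("lineage", "scaffold", "pos", "zygosity",
                                   "fold", "label"),
                     file.path(out_dir, "snv_classification.tsv"),
                     progress = FALSE)
    ann <- stage("snv_effect", annotate_snv_effect(snvs, genes, scaffolds))
    dnds <- gene_dn_ds(ann, genes, partition)
    report$dn_ds <- dnds$comparison
    report$syn_per_kb <- dnds$syn_per_kb
  } else {
    report$snv_summary <- "skipped"
  }

  tallies <- tally_superfamilies(features, partition)
  if (nrow(tallies) >= 2) {
    enr <- superfamily_enrichment(tallies, alpha = p$alpha)
    report$superfamily_enrichment <- as_tibble(enr)
    readr::write_tsv(enr, file.path(out_dir, "superfamily_enrichment.tsv"),
                     progress = FALSE)
  }
  report$length_polymorphism <- length_polymorphism(features, partition)

  gene_regions <- genes |>
    select("gene_id", "scaffold", "start", "end") |>
    assign_region(partition) |>
    select("gene_id", "region")
  profiles <- stage("cpg", gene_exon_cpg_oe(genes, scaffolds))
  report$cpg_medians <- profiles |>
    dplyr::inner_join(gene_regions, by = "gene_id") |>
    filter(!is.na(.data$oe), .data$region %in% c("island", "ldr")) |>
    group_by(.data$region) |>
    summarise(median_oe = median(.data$oe), n = dplyr::n(), .groups = "drop")
  if (!is.null(snvs)) {
    cons <- purrr::map(p$lineages, function(l) {
      gene_exon_cpg_oe(genes, substitute_snvs(scaffolds, snvs, l))
    })
    report$oe_ratio_ftest <- tryCatch(
      lineage_oe_ratio_test(cons[[1]], cons[[2]], gene_regions),
      error = function(e) "skipped"
    )
  }

  if (!is.null(inp$counts) && !is.null(inp$groups)) {
    counts <- stage("read_counts", read_count_tsv(inp$counts))
    gmap <- readr::read_tsv(inp$groups, col_types = "cc", progress = FALSE)
    groups <- setNames(gmap$group, gmap$sample)
    summaries <- stage("expression", mean_normalized_expression(counts, groups))
    expr <- compare_region_expression(summaries, gene_regions, p$groups)
    report$expression <- expr
    curve <- expression_rank_curve(summaries, profiles, gene_regions,
                                   bins = p$bins)
    readr::write_tsv(curve, file.path(out_dir, "expression_rank_curve.tsv"),
                     progress = FALSE)
  } else {
    report$expression <- "skipped"
    skipped <- c(skipped, "expression")
  }

  if (!is.null(inp$terms)) {
    terms <- read_term_tsv(inp$terms)
    isl_genes <- gene_regions$gene_id[gene_regions$region == "island"]
    report$term_enrichment <- as_tibble(term_enrichment_two_tailed(
      terms |> filter(.data$gene_id %in% gene_regions$gene_id),
      intersect(isl_genes, gene_regions$gene_id), gene_regions$gene_id,
      alpha = p$alpha
    ))
  }

  report$skipped_stages <- skipped
  write_partition_bed(partition, file.path(out_dir, "islands.bed"))
  readr::write_tsv(report$island_summary,
                   file.path(out_dir, "island_summary.tsv"), progress = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Compare a pipeline run against planted truth
#'
#' When a dataset directory contains `truth.json` (from
#' [simulate_dataset()]) and a pipeline output directory, reports the
#' island Jaccard index, recall/precision of collapsed-duplication SNV
#' classification, and direction-of-effect checks for the regional
#' statistics.
#'
#' @param dataset_dir Directory written by [simulate_dataset()].
#' @param out_dir Directory written by [run_pipeline()].
#' @return A list: `island_jaccard`, `duplication_recall`,
#'   `duplication_precision`, `directions` (named logical vector).
#' @export
check_recovery <- function(dataset_dir, out_dir) {
  truth_path <- file.path(dataset_dir, "truth.json")
  if (!file.exists(truth_path)) {
    inform("no truth.json present: nothing to check")
    return(invisible(NULL))
  }
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  report <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  called <- read_intervals_bed(file.path(out_dir, "islands.bed"))
  jac <- jaccard_intervals(as_tibble(truth$islands), called)

  recall <- NA_real_
  precision <- NA_real_
  cls_path <- file.path(out_dir, "snv_classification.tsv")
  if (file.exists(cls_path) && length(truth$snvs) > 0) {
    cls <- readr::read_tsv(cls_path, col_types = readr::cols(),
                           progress = FALSE)
    truth_snv <- as_tibble(truth$snvs)
    m <- cls |>
      dplyr::inner_join(truth_snv, by = c("scaffold", "pos"))
    planted <- m |> filter(.data$true_class == "collapsed_duplication",
                           .data$zygosity == "het")
    called_dup <- m |> filter(.data$label == "collapsed_duplication")
    if (nrow(planted) > 0) {
      recall <- mean(planted$label == "collapsed_duplication")
    }
    if (nrow(called_dup) > 0) {
      precision <- mean(called_dup$true_class == "collapsed_duplication")
    }
  }

  directions <- c(
    deviation = tryCatch(
      report$region_deviation$median_islands > report$region_deviation$median_ldr,
      error = function(e) NA
    ),
    expression = tryCatch({
      iv <- report$expression$island_vs_ldr
      iv$median_islands[iv$group == "base_mean"] <
        iv$median_ldr[iv$group == "base_mean"]
    }, error = function(e) NA),
    cpg = tryCatch({
      cm <- report$cpg_medians
      cm$median_oe[cm$region == "island"] < cm$median_oe[cm$region == "ldr"]
    }, error = function(e) NA)
  )
  list(island_jaccard = jac, duplication_recall = recall,
       duplication_precision = precision, directions = directions)
}
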