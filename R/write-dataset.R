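# Writers for the synthetic dataset: exactly the dialects the readers
# accept (FASTA, GFF3, VCF 4.2, samtools-depth TSV, counts TSV, truth
# JSON/BED).

write_fasta <- function(scaffolds, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(scaffolds))) {
    writeLines(paste0(">", scaffolds$scaffold[i]), con)
    s <- scaffolds$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(stringr::str_sub(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0) return(invisible(path))
  f <- features |> arrange(.data$scaffold, .data$start, .data$end)
  attrs <- purrr::pmap_chr(
    list(f$id, f$parent, f$te_class, f$superfamily),
    function(id, parent, te_class, superfamily) {
      parts <- c(
        if (!is.na(id)) paste0("ID=", id),
        if (!is.na(parent)) paste0("Parent=", parent),
        if (!is.na(te_class)) paste0("te_class=", te_class),
        if (!is.na(superfamily)) paste0("superfamily=", superfamily)
      )
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }
  )
  type <- ifelse(f$kind == "cds", "CDS", f$kind)
  writeLines(paste(f$scaffold, "teislandr", type, f$start, f$end, ".",
                   f$strand, ifelse(is.na(f$phase), ".", f$phase), attrs,
                   sep = "\t"), con)
  invisible(path)
}

write_vcf <- function(snvs, path, lineages = c("BR", "JP")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", lineages), collapse = "\t")
  ), con)
  if (nrow(snvs) == 0) return(invisible(path))
  gt_of <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1", missing = "./.")
  wide <- snvs |>
    mutate(gtdp = paste0(gt_of[.data$zygosity], ":", .data$depth)) |>
    select("scaffold", "pos", "ref", "alt", "lineage", "gtdp") |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "gtdp") |>
    arrange(.data$scaffold, .data$pos)
  body <- paste(wide$scaffold, wide$pos, ".", wide$ref, wide$alt, ".",
                "PASS", ".", "GT:DP", sep = "\t")
  for (l in lineages) body <- paste(body, wide[[l]], sep = "\t")
  writeLines(body, con)
  invisible(path)
}

write_depth_tsv <- function(depth, path) {
  readr::write_tsv(depth |> select("scaffold", "pos", "depth"), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the full generator for one seed and writes every file the analysis
#' pipeline reads, plus the ground truth (JSON and BED) and a parameter
#' echo, into `dir`.
#'
#' @param params A [sim_params()] list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   simulation objects (`genome`, `coverage`, `snv_sim`, `expr_sim`).
#' @export
simulate_dataset <- function(params = sim_params(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(params)
  coverage <- simulate_coverage(genome, params)
  snv_sim <- simulate_snvs(genome, params, coverage = coverage)
  expr_sim <- simulate_counts(genome, params)

  paths <- list(
    fasta = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "annotation.gff3"),
    vcf = file.path(dir, "snvs.vcf"),
    depth = setNames(
      file.path(dir, paste0("depth_", params$lineages, ".tsv")),
      params$lineages
    ),
    counts = file.path(dir, "counts.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth_json = file.path(dir, "truth.json"),
    truth_bed = file.path(dir, "truth_islands.bed"),
    params = file.path(dir, "params.yml")
  )
  write_fasta(genome$scaffolds, paths$fasta)
  write_gff3(genome$features, paths$gff)
  write_vcf(snv_sim$snvs, paths$vcf, lineages = params$lineages)
  for (l in params$lineages) write_depth_tsv(coverage[[l]], paths$depth[[l]])
  write_counts_tsv(expr_sim$counts, paths$counts)
  readr::write_tsv(tibble(sample = names(expr_sim$groups),
                          group = unname(expr_sim$groups)),
                   paths$groups, progress = FALSE)
  truth <- genome$truth
  jsonlite::write_json(
    list(
      islands = truth$islands,
      duplications = truth$duplications,
      genes = truth$genes |> select("gene_id", "region"),
      snvs = snv_sim$truth,
      seed = params$seed
    ),
    paths$truth_json, auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(
    truth$islands |>
      mutate(start0 = .data$start - 1L) |>
      select("scaffold", "start0", "end", "island_id"),
    paths$truth_bed, col_names = FALSE, progress = FALSE
  )
  p_echo <- unclass(params)
  p_echo$superfamilies <- as.data.frame(p_echo$superfamilies)
  yaml::write_yaml(p_echo, paths$params)
  invisible(c(paths, list(genome = genome, coverage = coverage,
                          snv_sim = snv_sim, expr_sim = expr_sim)))
}
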