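#' Read genome scaffolds from a FASTA file
#'
#' Reads a (multi-)FASTA of genome scaffolds into a tibble. Sequences are
#' uppercased; only `A`, `C`, `G`, `T` and `N` are accepted, because
#' downstream CpG counting must be well defined. Header descriptions after
#' the first whitespace are dropped from the scaffold id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `scaffold` (character), `length` (integer
#'   bp) and `sequence` (character). Empty files yield a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    return(tibble(scaffold = character(), length = integer(),
                  sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate scaffold id(s) in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(sprintf("scaffold %s contains characters other than A/C/G/T/N",
                  ids[which(bad)[1]]))
  }
  tibble(scaffold = unname(ids), length = unname(nchar(seqs)),
         sequence = unname(seqs))
}

#' Read annotation features from a GFF3 file
#'
#' Imports TE copies, genes, exons and CDS from GFF3. Feature types are
#' matched case-insensitively against `kinds`; unrequested types are
#' silently skipped. TE copies are expected to carry `superfamily` and
#' `te_class` attributes in column 9; exons and CDS carry `Parent`.
#' Lines with `start > end` are rejected with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param kinds Character vector of feature types to keep (GFF3 `type`
#'   column values); defaults to the four the pipeline uses.
#' @return A tibble with columns `scaffold`, `start`, `end` (1-based
#'   inclusive), `strand` (`+`, `-` or `.`), `kind` (one of `te_copy`,
#'   `gene`, `exon`, `cds`), `id`, `parent`, `te_class`, `superfamily`,
#'   `phase`. Attribute columns are `NA` where inapplicable.
#' @export
read_annotation_gff <- function(path, kinds = c("te_copy", "gene", "exon", "CDS")) {
  stopifnot(file.exists(path))
  raw <- suppressWarnings(rtracklayer::readGFF(path))
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  canon <- function(x) {
    x <- tolower(as.character(x))
    x[x == "transposable_element" | x == "te"] <- "te_copy"
    x
  }
  empty <- tibble(
    scaffold = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), id = character(),
    parent = character(), te_class = character(), superfamily = character(),
    phase = integer()
  )
  if (nrow(raw) == 0L) return(empty)
  keep <- canon(raw$type) %in% canon(kinds)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) return(empty)
  bad <- raw$start > raw$end
  if (any(bad)) {
    warn(sprintf("%d GFF line(s) with start > end rejected", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  get_attr <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    x <- raw[[col]]
    if (is.list(x)) x <- vapply(x, function(v) {
      if (length(v) == 0) NA_character_ else as.character(v[[1]])
    }, character(1))
    as.character(x)
  }
  tibble(
    scaffold = as.character(raw$seqid),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    strand = dplyr::coalesce(as.character(raw$strand), "."),
    kind = canon(raw$type),
    id = get_attr("ID"),
    parent = get_attr("Parent"),
    te_class = get_attr("te_class"),
    superfamily = get_attr("superfamily"),
    phase = suppressWarnings(as.integer(as.character(raw$phase)))
  ) |>
    arrange(.data$scaffold, .data$start, .data$end)
}

#' Read biallelic SNVs with per-lineage genotype and depth from a VCF
#'
#' Keeps biallelic single-nucleotide records only; indels, multiallelic and
#' symbolic records are skipped and their count reported via the
#' `n_skipped` attribute (and a message). Genotypes are mapped to zygosity
#' labels; per-sample `DP` is captured (0 when absent).
#'
#' @param path Path to a VCF 4.x file with one sample column per lineage.
#' @param lineages Character vector of sample names to extract, e.g.
#'   `c("BR", "JP")`. All must be present in the VCF header.
#' @return A long tibble with one row per SNV x lineage: columns
#'   `scaffold`, `pos`, `ref`, `alt`, `lineage`, `zygosity` (one of
#'   `hom_ref`, `hom_alt`, `het`, `missing`) and `depth`. The number of
#'   skipped non-SNV records is attached as attribute `n_skipped`.
#' @export
read_snv_vcf <- function(path, lineages = c("BR", "JP")) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  smp <- colnames(vcf@gt)[-1]
  missing_smp <- setdiff(lineages, smp)
  if (length(missing_smp) > 0) {
    abort(sprintf("lineage sample(s) absent from VCF: %s",
                  paste(missing_smp, collapse = ", ")))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  is_snv <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% nt & fix$ALT %in% nt
  n_skipped <- sum(!is_snv)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  map_zyg <- function(g) {
    g <- gsub("\\|", "/", g)
    dplyr::case_when(
      is.na(g) | g %in% c("./.", ".") ~ "missing",
      g %in% c("0/0", "0") ~ "hom_ref",
      g %in% c("1/1", "1") ~ "hom_alt",
      g %in% c("0/1", "1/0") ~ "het",
      TRUE ~ "missing"
    )
  }
  rows <- purrr::map(lineages, function(l) {
    tibble(
      scaffold = fix$CHROM[is_snv],
      pos = as.integer(fix$POS[is_snv]),
      ref = fix$REF[is_snv],
      alt = fix$ALT[is_snv],
      lineage = l,
      zygosity = map_zyg(gt[is_snv, l]),
      depth = {
        d <- dp[is_snv, l]
        as.integer(ifelse(is.na(d), 0, d))
      }
    )
  })
  out <- bind_rows(rows) |> arrange(.data$scaffold, .data$pos, .data$lineage)
  if (n_skipped > 0) {
    inform(sprintf("read_snv_vcf: skipped %d non-SNV record(s)", n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a samtools-depth style per-base depth table
#'
#' Expects three tab-separated columns: scaffold, 1-based position, depth.
#' Positions absent from the file are implicitly depth 0 (the table is kept
#' sparse; window averaging divides by window length, not rows present).
#'
#' @param path Path to the depth TSV (no header).
#' @param lineage Label attached to the track (column `lineage`).
#' @return A tibble with columns `lineage`, `scaffold`, `pos`, `depth`.
#' @export
read_depth_tsv <- function(path, lineage) {
  stopifnot(file.exists(path))
  d <- readr::read_tsv(path, col_names = c("scaffold", "pos", "depth"),
                       col_types = "cii", progress = FALSE)
  if (nrow(d) > 0 && any(d$depth < 0)) {
    abort(sprintf("negative depth in %s", path))
  }
  tibble(lineage = lineage, scaffold = d$scaffold, pos = d$pos,
         depth = d$depth)
}

#' Write a region partition as BED
#'
#' Emits one BED6-style line per island (0-based half-open coordinates,
#' name column = island id). Optionally the LDR complement is appended with
#' names `ldr_<n>`.
#'
#' @param partition A `region_partition` from [call_te_islands()].
#' @param path Output path.
#' @param include_ldr Also emit LDR intervals? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path, include_ldr = FALSE) {
  stopifnot(inherits(partition, "region_partition"))
  isl <- partition$islands |>
    mutate(name = .data$island_id)
  df <- isl |> select("scaffold", "start", "end", "name")
  if (include_ldr) {
    ldr <- partition$ldr |>
      mutate(name = paste0("ldr_", row_number())) |>
      select("scaffold", "start", "end", "name")
    df <- bind_rows(df, ldr)
  }
  df <- df |>
    arrange(.data$scaffold, .data$start) |>
    mutate(start0 = .data$start - 1L) |>
    select("scaffold", "start0", "end", "name")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read interval calls from a BED file
#'
#' Inverse of [write_partition_bed()] for round-tripping island calls:
#' converts 0-based half-open BED back to 1-based inclusive coordinates.
#'
#' @param path Path to a BED file (>= 3 columns, optional 4th name).
#' @return A tibble with columns `scaffold`, `start`, `end`, `name`.
#' @export
read_intervals_bed <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(scaffold = character(), start = integer(),
                  end = integer(), name = character()))
  }
  d <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  out <- tibble(
    scaffold = as.character(d[[1]]),
    start = as.integer(d[[2]]) + 1L,
    end = as.integer(d[[3]]),
    name = if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_
  )
  out
}

#' Read a gene x sample read-count table
#'
#' @param path TSV with a header row of sample ids and gene ids in the
#'   first column.
#' @return A tibble with a `gene_id` column followed by one integer column
#'   per sample. Negative counts are an error.
#' @export
read_count_tsv <- function(path) {
  stopifnot(file.exists(path))
  d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(d)[1] <- "gene_id"
  mat <- as.matrix(d[-1])
  if (any(mat < 0)) abort("negative counts in count table")
  d
}

#' Read a two-column gene-to-term map
#'
#' @param path TSV with columns gene id, term id (no header).
#' @return A tibble with columns `gene_id`, `term`.
#' @export
read_term_tsv <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(gene_id = character(), term = character()))
  }
  readr::read_tsv(path, col_names = c("gene_id", "term"), col_types = "cc",
                  progress = FALSE)
}

#' Assemble gene models from annotation features
#'
#' Collects exon and CDS features per gene into a nested tibble, checks the
#' exon/CDS structure and flags genes whose total CDS length is not a
#' multiple of 3 (their coding effects are later reported `unknown`).
#'
#' @param features Annotation tibble from [read_annotation_gff()] (needs
#'   `gene`, `exon` and `CDS` rows; exons/CDS linked to genes via `parent`).
#' @return A tibble with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `start`, `end`, `exons` and `cds` (list columns of start/end tibbles,
#'   sorted by genomic position), `cds_len`, `cds_complete` (divisible by
#'   3).
#' @export
gene_models <- function(features) {
  genes <- features |> filter(.data$kind == "gene")
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), scaffold = character(),
                  strand = character(), start = integer(), end = integer(),
                  exons = list(), cds = list(), cds_len = integer(),
                  cds_complete = logical()))
  }
  kids <- features |>
    filter(.data$kind %in% c("exon", "cds"), !is.na(.data$parent))
  nest_kid <- function(kind_want) {
    kids |>
      filter(.data$kind == kind_want) |>
      select("parent", "start", "end") |>
      arrange(.data$parent, .data$start) |>
      tidyr::nest(.by = "parent", .key = "ivs")
  }
  ex <- nest_kid("exon") |> rename(exons = "ivs")
  cd <- nest_kid("cds") |> rename(cds = "ivs")
  out <- genes |>
    select(gene_id = "id", "scaffold", "strand", "start", "end") |>
    left_join(ex, by = c(gene_id = "parent")) |>
    left_join(cd, by = c(gene_id = "parent"))
  empty_iv <- tibble(start = integer(), end = integer())
  out$exons <- purrr::map(out$exons, ~ .x %||% empty_iv)
  out$cds <- purrr::map(out$cds, ~ .x %||% empty_iv)
  out |>
    mutate(
      cds_len = purrr::map_int(.data$cds, ~ sum(.x$end - .x$start + 1L)),
      cds_complete = .data$cds_len > 0L & .data$cds_len %% 3L == 0L
    )
}
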