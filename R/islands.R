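#' Call TE islands from a sliding 200 kb density track
#'
#' Partitions the eligible portion of a genome (scaffolds at least
#' `min_scaffold` bp) into TE islands and low-density regions (LDRs).
#' Islands are seeded by sliding windows whose TE bp falls in the upper
#' `1 - quantile` tail (>= the empirical type-7 quantile of TE bp over all
#' eligible-scaffold windows, i.e. the closed 95--100% band at the
#' default); qualifying windows are unioned per scaffold into maximal
#' intervals. Interval edges are then refined at 1 kb resolution by
#' trimming terminal 1 kb tiles whose TE fraction is below the global
#' median 1 kb TE fraction, and intervals shorter than `min_island` are
#' dropped. Everything else on eligible scaffolds is LDR.
#'
#' @param track200 Sliding-window track from [aggregate_windows()].
#' @param track1kb The underlying 1 kb tiling from [tile_windows()], used
#'   for edge trimming.
#' @param scaffold_lengths Named vector or scaffold/length data frame.
#' @param quantile Lower bound of the qualifying TE-content quantile band
#'   (default 0.95).
#' @param min_scaffold Minimum scaffold length in bp for eligibility
#'   (default 200000).
#' @param min_island Minimum island length in bp after trimming (default
#'   10000).
#' @param per_scaffold Compute the quantile threshold per scaffold instead
#'   of globally (default `FALSE`; the global threshold is what keeps
#'   islands confined to genuinely TE-dense scaffolds).
#' @return A `region_partition` object: a list with `islands` (tibble
#'   `island_id`, `scaffold`, `start`, `end`, `te_fraction`), `ldr`
#'   (complement tibble), `scaffolds` (eligible scaffold/length tibble) and
#'   `threshold`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
call_te_islands <- function(track200, track1kb, scaffold_lengths,
                            quantile = 0.95, min_scaffold = 200000,
                            min_island = 10000, per_scaffold = FALSE) {
  stopifnot(quantile >= 0, quantile <= 1, min_island >= 0)
  sl <- as_scaffold_lengths(scaffold_lengths)
  eligible <- sl[sl >= min_scaffold]
  if (length(eligible) == 0) abort("no scaffolds pass min_scaffold")

  t200 <- track200 |> as_tibble() |> filter(.data$scaffold %in% names(eligible))
  if (nrow(t200) == 0) abort("no aggregate windows on eligible scaffolds")
  t1 <- track1kb |> as_tibble() |> filter(.data$scaffold %in% names(eligible))
  ws1 <- attr(track1kb, "window_size")

  if (per_scaffold) {
    t200 <- t200 |>
      group_by(.data$scaffold) |>
      mutate(.thr = stats::quantile(.data$te_bp, quantile, type = 7)) |>
      ungroup()
    threshold <- stats::quantile(t200$te_bp, quantile, type = 7)
  } else {
    threshold <- stats::quantile(t200$te_bp, quantile, type = 7)
    t200$.thr <- threshold
  }
  if (length(unique(t200$te_bp)) == 1L && any(t200$te_bp > 0)) {
    warn("degenerate TE density: all aggregate windows equal; every window qualifies")
  }
  # TE-free windows can never seed an island, whatever the quantile says
  qual <- t200 |> filter(.data$te_bp >= .data$.thr, .data$te_bp > 0)

  median_frac <- median(t1$te_bp / t1$effective_len)

  islands <- if (nrow(qual) == 0) {
    tibble(scaffold = character(), start = integer(), end = integer())
  } else {
    qual |>
      group_by(.data$scaffold) |>
      dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
      ungroup()
  }

  trim_one <- function(sc, s, e) {
    tiles <- t1 |>
      filter(.data$scaffold == sc, .data$start >= s, .data$end <= e) |>
      arrange(.data$start)
    if (nrow(tiles) == 0) return(NULL)
    frac <- tiles$te_bp / tiles$effective_len
    lo <- 1L
    hi <- nrow(tiles)
    while (lo <= hi && frac[lo] < median_frac) lo <- lo + 1L
    while (hi >= lo && frac[hi] < median_frac) hi <- hi - 1L
    if (lo > hi) return(NULL)
    tibble(scaffold = sc, start = tiles$start[lo], end = tiles$end[hi])
  }

  if (nrow(islands) > 0) {
    islands <- purrr::pmap(
      list(islands$scaffold, islands$start, islands$end), trim_one
    ) |>
      purrr::compact() |>
      bind_rows()
  }
  if (nrow(islands) > 0) {
    islands <- islands |>
      filter(.data$end - .data$start + 1 >= min_island) |>
      arrange(.data$scaffold, .data$start)
  }

  te_frac_of <- function(sc, s, e) {
    tiles <- t1 |> filter(.data$scaffold == sc, .data$start >= s, .data$end <= e)
    if (nrow(tiles) == 0) return(NA_real_)
    sum(tiles$te_bp) / sum(tiles$effective_len)
  }
  islands <- islands |>
    mutate(
      island_id = paste0("island_", row_number()),
      te_fraction = purrr::pmap_dbl(
        list(.data$scaffold, .data$start, .data$end), te_frac_of
      )
    ) |>
    select("island_id", "scaffold", "start", "end", "te_fraction")

  ldr <- purrr::map(names(eligible), function(sc) {
    L <- as.integer(eligible[[sc]])
    isl <- islands |> filter(.data$scaffold == sc)
    if (nrow(isl) == 0) return(tibble(scaffold = sc, start = 1L, end = L))
    gaps <- IRanges::setdiff(
      IRanges::IRanges(1L, L),
      IRanges::IRanges(isl$start, isl$end)
    )
    if (length(gaps) == 0) return(NULL)
    tibble(scaffold = sc, start = BiocGenerics::start(gaps),
           end = BiocGenerics::end(gaps))
  }) |> purrr::compact() |> bind_rows()

  out <- region_partition(islands, eligible)
  out$threshold <- unname(threshold)
  out$params <- list(quantile = quantile, min_scaffold = min_scaffold,
                     min_island = min_island, per_scaffold = per_scaffold,
                     trim_median_te_fraction = median_frac,
                     resolution = ws1)
  out
}

#' Construct a region partition from island intervals
#'
#' Builds the island/LDR two-way partition object directly from a table of
#' island calls, e.g. to apply the divergence and composition statistics to
#' externally derived islands. Islands must be non-overlapping and lie on
#' the given scaffolds; the LDR compartment is the complement.
#'
#' @param islands Tibble with `scaffold`, `start`, `end` (1-based
#'   inclusive) and optionally `island_id` and `te_fraction`.
#' @param scaffold_lengths Named vector or scaffold/length data frame of
#'   the eligible scaffolds.
#' @return A `region_partition` object.
#' @export
region_partition <- function(islands, scaffold_lengths) {
  sl <- as_scaffold_lengths(scaffold_lengths)
  islands <- as_tibble(islands)
  if (nrow(islands) > 0) {
    check_known_scaffolds(islands$scaffold, sl, "islands")
    if (!"island_id" %in% names(islands)) {
      islands <- islands |> mutate(island_id = paste0("island_", row_number()))
    }
    if (!"te_fraction" %in% names(islands)) islands$te_fraction <- NA_real_
    islands <- islands |>
      arrange(.data$scaffold, .data$start) |>
      select("island_id", "scaffold", "start", "end", "te_fraction")
    if (any(islands$start > islands$end) || any(islands$start < 1) ||
        any(islands$end > sl[islands$scaffold])) {
      abort("island intervals outside scaffold bounds")
    }
    merged_bp <- sum(purrr::map_dbl(unique(islands$scaffold), function(sc) {
      i <- islands |> filter(.data$scaffold == sc)
      union_bp(i$start, i$end)
    }))
    if (merged_bp != sum(islands$end - islands$start + 1)) {
      abort("islands overlap")
    }
  } else {
    islands <- tibble(island_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      te_fraction = numeric())
  }
  ldr <- purrr::map(names(sl), function(sc) {
    L <- as.integer(sl[[sc]])
    isl <- islands |> filter(.data$scaffold == sc)
    if (nrow(isl) == 0) return(tibble(scaffold = sc, start = 1L, end = L))
    gaps <- IRanges::setdiff(
      IRanges::IRanges(1L, L),
      IRanges::IRanges(isl$start, isl$end)
    )
    if (length(gaps) == 0) return(NULL)
    tibble(scaffold = sc, start = BiocGenerics::start(gaps),
           end = BiocGenerics::end(gaps))
  }) |> purrr::compact() |> bind_rows()
  structure(
    list(islands = islands, ldr = ldr,
         scaffolds = tibble(scaffold = names(sl), length = as.numeric(sl)),
         threshold = NA_real_, params = list()),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "TE island partition: %d island(s), %.2f Mb island / %.2f Mb eligible (%d scaffold(s))\n",
    nrow(x$islands),
    sum(x$islands$end - x$islands$start + 1) / 1e6,
    sum(x$scaffolds$length) / 1e6,
    nrow(x$scaffolds)
  ))
  print(x$islands, ...)
  invisible(x)
}

#' Assign intervals or sites to island / LDR compartments
#'
#' Midpoint rule: a record belongs to the island that contains the midpoint
#' of its interval (for a site, the position itself). Records on
#' non-eligible scaffolds are labelled `unassigned`.
#'
#' @param x A tibble with `scaffold` and either `pos` or `start`/`end`.
#' @param partition A `region_partition`.
#' @return `x` with columns `region` (`island`, `ldr` or `unassigned`) and
#'   `island_id` (`NA` outside islands).
#' @export
assign_region <- function(x, partition) {
  stopifnot(inherits(partition, "region_partition"))
  mid <- if ("pos" %in% names(x)) {
    x$pos
  } else {
    (x$start + x$end) %/% 2
  }
  region <- ifelse(x$scaffold %in% partition$scaffolds$scaffold,
                   "ldr", "unassigned")
  island_id <- rep(NA_character_, nrow(x))
  isl <- partition$islands
  if (nrow(isl) > 0 && nrow(x) > 0) {
    q <- IRanges::IRanges(start = mid, width = 1L)
    s <- IRanges::IRanges(start = isl$start, end = isl$end)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same <- x$scaffold[qh] == isl$scaffold[sh]
    island_id[qh[same]] <- isl$island_id[sh[same]]
    region[!is.na(island_id) & region == "ldr"] <- "island"
  }
  x |> mutate(region = region, island_id = island_id)
}

#' Summarise a TE island partition
#'
#' Headline statistics of the island/LDR split: island count and span,
#' island share of the assembly, TE sequence inside islands and its share
#' of all TE sequence, genes whose midpoint lies in an island, and exon
#' density (exon bp per kb) in islands versus LDRs.
#'
#' @param partition A `region_partition`.
#' @param features Annotation tibble (kinds `te_copy` and `exon` used);
#'   may be `NULL`.
#' @param genes Gene tibble with `scaffold`, `start`, `end` (e.g. kind ==
#'   "gene" rows, or [gene_models()] output); may be `NULL`.
#' @param assembly_len Total assembly length in bp.
#' @return A one-row tibble: `n_islands`, `island_bp`, `island_pct`
#'   (percent of `assembly_len`), `te_bp_islands`, `te_bp_total`,
#'   `te_pct_in_islands`, `n_genes_islands`, `n_genes`, `gene_pct_islands`,
#'   `exon_bp_per_kb_islands`, `exon_bp_per_kb_ldr`.
#' @export
island_summary <- function(partition, features = NULL, genes = NULL,
                           assembly_len) {
  stopifnot(inherits(partition, "region_partition"), assembly_len > 0)
  isl <- partition$islands
  island_bp <- sum(isl$end - isl$start + 1)
  ldr_bp <- sum(partition$ldr$end - partition$ldr$start + 1)

  region_bp_of <- function(f) {
    # union-merge per scaffold, then split bp exactly at island boundaries
    if (is.null(f) || nrow(f) == 0) return(c(island = 0, total = 0, eligible = 0))
    tot <- 0
    in_isl <- 0
    elig <- 0
    for (sc in unique(f$scaffold)) {
      fs <- f |> filter(.data$scaffold == sc)
      m <- merge_intervals(fs$start, fs$end)
      tot <- tot + sum(m$end - m$start + 1)
      if (sc %in% partition$scaffolds$scaffold) {
        elig <- elig + sum(m$end - m$start + 1)
      }
      is_sc <- isl |> filter(.data$scaffold == sc)
      if (nrow(is_sc) > 0) {
        in_isl <- in_isl + sum(overlap_bp(is_sc$start, is_sc$end,
                                          m$start, m$end))
      }
    }
    c(island = in_isl, total = tot, eligible = elig)
  }
  te <- region_bp_of(if (is.null(features)) NULL else
    features |> filter(.data$kind == "te_copy"))
  ex <- region_bp_of(if (is.null(features)) NULL else
    features |> filter(.data$kind == "exon"))

  n_genes <- if (is.null(genes)) 0L else nrow(genes)
  n_genes_isl <- 0L
  if (!is.null(genes) && nrow(genes) > 0) {
    g <- assign_region(genes, partition)
    n_genes_isl <- sum(g$region == "island")
  }

  tibble(
    n_islands = nrow(isl),
    island_bp = island_bp,
    island_pct = 100 * island_bp / assembly_len,
    te_bp_islands = unname(te["island"]),
    te_bp_total = unname(te["total"]),
    te_pct_in_islands = if (te["total"] > 0) 100 * unname(te["island"] / te["total"]) else NA_real_,
    n_genes_islands = n_genes_isl,
    n_genes = n_genes,
    gene_pct_islands = if (n_genes > 0) 100 * n_genes_isl / n_genes else NA_real_,
    exon_bp_per_kb_islands = if (island_bp > 0) 1000 * unname(ex["island"]) / island_bp else NA_real_,
    exon_bp_per_kb_ldr = if (ldr_bp > 0) 1000 * (unname(ex["eligible"] - ex["island"])) / ldr_bp else NA_real_
  )
}
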