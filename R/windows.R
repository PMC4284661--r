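#' Tile scaffolds into fixed windows of annotation density
#'
#' Tiles every scaffold into non-overlapping windows of `window_size` bp
#' (the terminal window may be shorter; its true extent is kept in
#' `effective_len`) and counts, per window: TE bp and exon bp (overlapping
#' annotations are union-merged first, so counts never exceed the window),
#' SNV calls per lineage and zygosity, and mean read depth per lineage
#' (sum of per-base depth divided by `effective_len`; absent positions
#' count as depth 0).
#'
#' @param features Annotation tibble (see [read_annotation_gff()]); rows of
#'   kind `te_copy` and `exon` are used.
#' @param scaffold_lengths Named numeric vector or scaffold/length data
#'   frame covering every scaffold referenced by the inputs.
#' @param snvs Optional long SNV tibble (see [read_snv_vcf()]).
#' @param coverage Optional depth tibble(s): either one tibble with columns
#'   `lineage`, `scaffold`, `pos`, `depth` (see [read_depth_tsv()]) or a
#'   list of them.
#' @param window_size Window width in bp (default 1000).
#' @return A `window_track` tibble: `scaffold`, `start`, `end`,
#'   `effective_len`, `te_bp`, `exon_bp`, then `snv_<zygosity>_<lineage>`
#'   count columns and `depth_<lineage>` mean-depth columns for the inputs
#'   supplied. Window size and step are carried as attributes.
#' @export
tile_windows <- function(features, scaffold_lengths, snvs = NULL,
                         coverage = NULL, window_size = 1000) {
  stopifnot(window_size >= 1)
  sl <- as_scaffold_lengths(scaffold_lengths)
  if (!is.null(features) && nrow(features) > 0) {
    check_known_scaffolds(features$scaffold, sl, "annotation features")
  }
  if (!is.null(snvs) && nrow(snvs) > 0) {
    check_known_scaffolds(snvs$scaffold, sl, "SNVs")
  }
  if (!is.null(coverage)) {
    if (is.data.frame(coverage)) coverage <- list(coverage)
    for (cv in coverage) {
      if (nrow(cv) > 0) check_known_scaffolds(cv$scaffold, sl, "depth records")
    }
  }

  n_win <- ceiling(sl / window_size)
  offset <- c(0, cumsum(n_win))[seq_along(sl)]  # rows before each scaffold
  win <- purrr::map(names(sl), function(sc) {
    L <- sl[[sc]]
    starts <- seq(1, L, by = window_size)
    tibble(
      scaffold = sc,
      start = as.integer(starts),
      end = as.integer(pmin(starts + window_size - 1, L))
    )
  }) |> bind_rows() |>
    mutate(effective_len = .data$end - .data$start + 1L)
  # row index of the window containing (scaffold, pos); win is in names(sl)
  # scaffold order until the final sort
  row_of <- function(scaffold, pos) {
    offset[match(scaffold, names(sl))] + (pos - 1) %/% window_size + 1
  }

  count_kind <- function(kind_want, col) {
    out <- integer(nrow(win))
    if (!is.null(features)) {
      f <- features |> filter(.data$kind == kind_want)
      for (sc in unique(f$scaffold)) {
        idx <- which(win$scaffold == sc)
        fs <- f |> filter(.data$scaffold == sc)
        out[idx] <- overlap_bp(win$start[idx], win$end[idx],
                               pmax(fs$start, 1L),
                               pmin(fs$end, as.integer(sl[[sc]])))
      }
    }
    win[[col]] <<- out
    invisible(NULL)
  }
  count_kind("te_copy", "te_bp")
  count_kind("exon", "exon_bp")

  if (!is.null(snvs) && nrow(snvs) > 0) {
    for (l in unique(snvs$lineage)) for (z in unique(snvs$zygosity)) {
      col <- paste("snv", z, l, sep = "_")
      sub <- snvs |> filter(.data$lineage == l, .data$zygosity == z)
      win[[col]] <- 0L
      if (nrow(sub) > 0) {
        tab <- tabulate(row_of(sub$scaffold, sub$pos), nbins = nrow(win))
        win[[col]] <- tab
      }
    }
  }

  if (!is.null(coverage)) {
    for (cv in coverage) {
      l <- unique(cv$lineage)
      stopifnot(length(l) == 1)
      col <- paste0("depth_", l)
      win[[col]] <- 0
      if (nrow(cv) > 0) {
        idx <- row_of(cv$scaffold, cv$pos)
        s <- rowsum(as.numeric(cv$depth), idx)
        win[[col]][as.integer(rownames(s))] <- s[, 1]
      }
      win[[col]] <- win[[col]] / win$effective_len
    }
  }

  new_window_track(win, window_size = window_size, step = window_size)
}

new_window_track <- function(df, window_size, step) {
  df <- df |> arrange(.data$scaffold, .data$start)
  attr(df, "window_size") <- window_size
  attr(df, "step") <- step
  class(df) <- c("window_track", class(df))
  df
}

#' Aggregate a 1 kb track into large sliding windows
#'
#' Slides a window of `span` bp along each scaffold in `step` bp increments
#' and sums the constituent fixed windows' counts. Windows that would
#' extend past the scaffold end are not emitted, so every emitted window
#' has `effective_len == span`; scaffolds shorter than `span` contribute no
#' windows. Mean-depth columns are recomputed as length-weighted means.
#'
#' @param track A complete tiling `window_track` (from [tile_windows()]).
#' @param span Width of the aggregate window in bp (default 200000); must
#'   be a multiple of the track's window size.
#' @param step Slide increment in bp (default 1000); must be a multiple of
#'   the track's window size.
#' @return A `window_track` tibble of sliding windows with summed count
#'   columns.
#' @export
aggregate_windows <- function(track, span = 200000, step = 1000) {
  ws <- attr(track, "window_size")
  stopifnot(!is.null(ws), span %% ws == 0, step %% ws == 0, span >= ws)
  k <- span %/% ws
  s <- step %/% ws
  sum_cols <- grep("^(te_bp|exon_bp|snv_)", names(track), value = TRUE)
  depth_cols <- grep("^depth_", names(track), value = TRUE)

  per_scaffold <- function(df) {
    df <- df |> arrange(.data$start)
    n <- nrow(df)
    scaffold_len <- df$end[n]
    # candidate start indices: windows of k consecutive 1 kb tiles whose
    # span fits entirely on the scaffold
    idx <- seq(1, n, by = s)
    starts <- df$start[idx]
    ok <- starts + span - 1 <= scaffold_len
    idx <- idx[ok]
    if (length(idx) == 0) return(NULL)
    out <- tibble(
      scaffold = df$scaffold[1],
      start = df$start[idx],
      end = as.integer(df$start[idx] + span - 1),
      effective_len = as.integer(span)
    )
    for (col in sum_cols) {
      cs <- c(0, cumsum(as.numeric(df[[col]])))
      out[[col]] <- cs[idx + k] - cs[idx]
    }
    for (col in depth_cols) {
      cs <- c(0, cumsum(as.numeric(df[[col]]) * df$effective_len))
      out[[col]] <- (cs[idx + k] - cs[idx]) / span
    }
    out
  }

  pieces <- track |>
    as_tibble() |>
    dplyr::group_split(.data$scaffold) |>
    purrr::map(per_scaffold) |>
    purrr::compact()
  out <- if (length(pieces) == 0) {
    track |> as_tibble() |> dplyr::slice(0) |>
      select(all_of(c("scaffold", "start", "end", "effective_len",
                      sum_cols, depth_cols)))
  } else {
    bind_rows(pieces)
  }
  new_window_track(out, window_size = span, step = step)
}
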