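# Internal interval helpers. All coordinates are 1-based inclusive (GFF
# convention); conversion to 0-based half-open happens only at BED boundaries.

#' @importFrom rlang .data %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n across all_of any_of if_else row_number
#'   rename count distinct pull slice
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl
#' @importFrom stats median quantile rpois rnbinom rbinom runif rnorm setNames
#'   complete.cases
NULL

# Merge (union) a set of 1-based inclusive intervals; returns a tibble with
# columns start, end sorted and non-overlapping. Book-ended intervals
# ([1,5],[6,9]) are merged, matching IRanges::reduce semantics.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  red <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  tibble(start = BiocGenerics::start(red), end = BiocGenerics::end(red))
}

# Total bp of the union of a set of intervals.
union_bp <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start + 1)
}

# For each query interval, bp of overlap with the union of subject intervals.
# Both sets 1-based inclusive; queries may overlap each other (e.g. sliding
# windows); subjects are reduced first.
overlap_bp <- function(q_start, q_end, s_start, s_end) {
  n <- length(q_start)
  if (n == 0L) return(integer())
  if (length(s_start) == 0L) return(integer(n))
  q <- IRanges::IRanges(start = q_start, end = q_end)
  s <- IRanges::reduce(IRanges::IRanges(start = s_start, end = s_end))
  hits <- IRanges::findOverlaps(q, s)
  if (length(hits) == 0L) return(integer(n))
  inter <- IRanges::pintersect(
    q[S4Vectors::queryHits(hits)],
    s[S4Vectors::subjectHits(hits)]
  )
  out <- integer(n)
  w <- rowsum(BiocGenerics::width(inter), S4Vectors::queryHits(hits))
  out[as.integer(rownames(w))] <- as.integer(w[, 1])
  out
}

# Normalise scaffold lengths input: accepts a named numeric vector or a
# two-column data frame (scaffold, length); returns a named numeric vector.
as_scaffold_lengths <- function(scaffold_lengths) {
  if (is.data.frame(scaffold_lengths)) {
    stopifnot(all(c("scaffold", "length") %in% names(scaffold_lengths)))
    out <- setNames(as.numeric(scaffold_lengths$length),
                    as.character(scaffold_lengths$scaffold))
  } else {
    if (is.null(names(scaffold_lengths))) {
      abort("scaffold_lengths must be a named vector or a scaffold/length data frame")
    }
    out <- setNames(as.numeric(scaffold_lengths), names(scaffold_lengths))
  }
  if (anyDuplicated(names(out))) abort("duplicate scaffold ids in scaffold_lengths")
  if (any(out <= 0)) abort("scaffold lengths must be positive")
  out
}

feature_tibble_empty <- function() {
  tibble(scaffold = character(), start = integer(), end = integer(),
         strand = character(), kind = character(), id = character(),
         parent = character(), te_class = character(),
         superfamily = character(), phase = integer())
}

check_known_scaffolds <- function(scaffolds, known, what) {
  bad <- setdiff(unique(as.character(scaffolds)), names(known))
  if (length(bad) > 0) {
    abort(sprintf("%s refer to unknown scaffold(s): %s",
                  what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
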