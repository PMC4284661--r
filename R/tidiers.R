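#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a region partition into its island table
#'
#' @param x A `region_partition`.
#' @param ... Unused.
#' @return The island tibble (`island_id`, `scaffold`, `start`, `end`,
#'   `te_fraction`).
#' @export
tidy.region_partition <- function(x, ...) {
  x$islands
}

#' One-row summary of a region partition
#'
#' @param x A `region_partition`.
#' @param ... Unused.
#' @return A one-row tibble: `n_islands`, `island_bp`, `ldr_bp`,
#'   `eligible_bp`, `island_fraction`, `threshold_te_bp`,
#'   `n_eligible_scaffolds`.
#' @export
glance.region_partition <- function(x, ...) {
  island_bp <- sum(x$islands$end - x$islands$start + 1)
  eligible_bp <- sum(x$scaffolds$length)
  tibble(
    n_islands = nrow(x$islands),
    island_bp = island_bp,
    ldr_bp = sum(x$ldr$end - x$ldr$start + 1),
    eligible_bp = eligible_bp,
    island_fraction = island_bp / eligible_bp,
    threshold_te_bp = x$threshold,
    n_eligible_scaffolds = nrow(x$scaffolds)
  )
}
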