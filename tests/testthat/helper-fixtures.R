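# Small in-code fixtures shared across test files.

feature_row <- function(scaffold, start, end, kind, strand = "+",
                        id = NA_character_, parent = NA_character_,
                        te_class = NA_character_,
                        superfamily = NA_character_, phase = NA_integer_) {
  tibble::tibble(scaffold = scaffold, start = as.integer(start),
                 end = as.integer(end), strand = strand, kind = kind,
                 id = id, parent = parent, te_class = te_class,
                 superfamily = superfamily, phase = phase)
}

te_row <- function(scaffold, start, end, superfamily = "Gypsy",
                   te_class = "I") {
  feature_row(scaffold, start, end, "te_copy", te_class = te_class,
              superfamily = superfamily)
}

# A partition with one island per row of `islands`.
toy_partition <- function(islands, scaffold_lengths) {
  region_partition(islands, scaffold_lengths)
}

# Long-format SNV rows for one lineage.
snv_rows <- function(scaffold, pos, lineage = "BR", zygosity = "hom_alt",
                     depth = 30L, ref = "A", alt = "G") {
  tibble::tibble(scaffold = scaffold, pos = as.integer(pos), ref = ref,
                 alt = alt, lineage = lineage, zygosity = zygosity,
                 depth = as.integer(depth))
}

depth_rows <- function(scaffold, pos, depth, lineage = "BR") {
  tibble::tibble(lineage = lineage, scaffold = scaffold,
                 pos = as.integer(pos), depth = as.integer(depth))
}

# Per-base bitmap oracle for windowed union bp of intervals.
bitmap_window_bp <- function(starts, ends, scaffold_len, window_size) {
  hit <- logical(scaffold_len)
  for (i in seq_along(starts)) {
    s <- max(1, starts[i])
    e <- min(scaffold_len, ends[i])
    if (s <= e) hit[s:e] <- TRUE
  }
  win <- (seq_len(scaffold_len) - 1) %/% window_size
  as.integer(tapply(hit, win, sum))
}

# Small genome parameters used where the full 3 x 2 Mb conditions are not
# the point of the test.
small_sim_params <- function(seed = 1, ...) {
  sim_params(
    seed = seed,
    n_scaffolds = 2L,
    scaffold_len = 4e5,
    n_islands = 1L,
    island_len = c(8e4, 8e4),
    island_margin = 3e4,
    n_duplications = 2L,
    duplication_len = 5e3,
    ...
  )
}
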