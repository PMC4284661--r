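#' Default simulation parameters
#'
#' The defaults describe the genome structure the analysis assumes: three
#' 2 Mb scaffolds carrying two planted 300 kb TE islands, TE occupancy 0.45
#' inside islands versus 0.05 outside with longer island copies, homozygous
#' SNV rates of 2/kb (island) versus 0.5/kb (LDR), rare true heterozygous
#' calls plus dense spurious het calls inside planted collapsed
#' duplications, 60x pooled coverage per lineage with stronger
#' multi-mapping noise in islands, CpG-depleted and weakly expressed island
#' genes, and a 7 + 7 queen/larva negative-binomial expression design.
#'
#' @param seed Integer seed; every simulation output is deterministic given
#'   it.
#' @param ... Overrides for any default listed below.
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(seed = 1, ...) {
  p <- list(
    seed = as.integer(seed),
    n_scaffolds = 3L,
    scaffold_len = 2e6,
    n_islands = 2L,
    island_len = c(3e5, 3e5),          # min, max planted island length
    island_margin = 5e4,               # keep islands off scaffold ends
    te_density = c(island = 0.45, ldr = 0.05),
    te_len_meanlog = c(island = log(3000), ldr = log(800)),
    te_len_sdlog = 0.6,
    superfamilies = tibble(
      superfamily = c("Gypsy", "Copia", "BEL-Pao", "R1", "hAT",
                      "TcMar-Mariner", "Maverick", "Merlin"),
      te_class = c("I", "I", "I", "I", "II", "II", "II", "II"),
      weight = c(3, 2, 1, 1, 2, 1, 1, 1),
      island_bias = c(1, 1, 3, 1, 1, 3, 1, 1)
    ),
    gene_per_kb = 0.1,
    exon_codons = c(50L, 150L),
    n_exons = c(2L, 5L),
    intron_len = c(100L, 500L),
    hom_snv_per_kb = c(island = 2, ldr = 0.5),
    het_snv_per_kb = c(island = 0.05, ldr = 0.02),
    n_duplications = 4L,
    duplication_len = 1e4,
    dup_het_per_kb = 5,
    depth = 60,
    ratio_noise_sd = c(island = 0.18, ldr = 0.08),
    cpg_conversion_max = c(island = 0.7, ldr = 0.2),
    expr_base_mean = 50,
    expr_sdlog = 1,
    expr_island_down = 0.02,
    expr_island_group_effect = 3,
    expr_dispersion = 0.3,
    n_queens = 7L,
    n_larvae = 7L,
    lineages = c("BR", "JP")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    abort(sprintf("unknown simulation parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  if (any(p$te_density < 0) || any(p$te_density > 1)) {
    abort("TE densities must lie in [0, 1]")
  }
  structure(p, class = c("sim_params", "list"))
}

# Place n non-overlapping blocks with the given lengths uniformly inside
# [1, region_len]; returns start positions (relative, 1-based). The gaps
# between blocks are a uniform random composition of the slack.
place_blocks <- function(lens, region_len) {
  n <- length(lens)
  if (n == 0) return(integer())
  slack <- region_len - sum(lens)
  if (slack < 0) abort("blocks exceed region length (density implies > 100% occupancy)")
  cuts <- sort(runif(n, 0, slack))
  gaps <- diff(c(0, cuts))
  starts <- integer(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- as.integer(floor(pos)) + 1L
    pos <- pos + lens[i]
  }
  starts
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
        1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

# Random valid ORF of n_codons codons: ATG start, sense body, stop end.
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  body <- sample(SENSE_CODONS, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# Convert a fraction of CG dinucleotides in an ORF to TG (the methylation
# footprint), skipping conversions that would create a stop codon.
deplete_cpg <- function(orf, p_convert) {
  if (p_convert <= 0) return(orf)
  x <- strsplit(orf, "")[[1]]
  cg <- which(x[-length(x)] == "C" & x[-1] == "G")
  cg <- cg[runif(length(cg)) < p_convert]
  for (i in cg) {
    old <- x[i]
    x[i] <- "T"
    codon_i <- (i - 1) %/% 3
    cod <- paste(x[(codon_i * 3 + 1):(codon_i * 3 + 3)], collapse = "")
    if (cod %in% STOP_CODONS && codon_i < length(x) / 3 - 1) x[i] <- old
    if (codon_i == 0) x[i] <- old  # never touch the start codon
  }
  paste(x, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a genome with planted TE islands
#'
#' Generates scaffold sequences (uniform base composition), plants TE
#' islands, places non-overlapping TE copy annotations at the region
#' densities with region-specific length distributions and
#' superfamily weights, lays out genes (exon = CDS, valid ORFs) that avoid
#' >= 50% TE overlap, applies CpG -> TpG conversion to gene exons at a
#' region- and expression-coupled rate, and plants collapsed-duplication
#' intervals inside islands.
#'
#' @param params A [sim_params()] list.
#' @return A list: `scaffolds` (tibble as from [read_genome_fasta()]),
#'   `features` (annotation tibble as from [read_annotation_gff()]) and
#'   `truth` (list with `islands`, `duplications`, `genes` including latent
#'   expression scores, and a `params` echo).
#' @export
simulate_genome <- function(params = sim_params()) {
  set.seed(params$seed)
  sc_ids <- sprintf("scf%02d", seq_len(params$n_scaffolds))
  L <- as.integer(params$scaffold_len)
  seqs <- lapply(sc_ids, function(x) sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seqs) <- sc_ids

  # plant islands on distinct scaffolds
  if (params$n_islands > params$n_scaffolds) {
    abort("more islands than scaffolds: place at most one per scaffold")
  }
  isl_sc <- sample(sc_ids, params$n_islands)
  isl_len <- as.integer(round(runif(params$n_islands, params$island_len[1],
                                    params$island_len[2])))
  isl_start <- as.integer(floor(runif(
    params$n_islands, params$island_margin,
    L - params$island_margin - isl_len
  ))) + 1L
  truth_islands <- tibble(
    island_id = paste0("true_island_", seq_len(params$n_islands)),
    scaffold = isl_sc, start = isl_start,
    end = isl_start + isl_len - 1L
  ) |> arrange(.data$scaffold, .data$start)

  # region map per scaffold: island intervals + LDR complement
  regions <- purrr::map(sc_ids, function(sc) {
    isl <- truth_islands |> filter(.data$scaffold == sc)
    ldr <- if (nrow(isl) == 0) {
      tibble(start = 1L, end = L)
    } else {
      gaps <- IRanges::setdiff(IRanges::IRanges(1L, L),
                               IRanges::IRanges(isl$start, isl$end))
      tibble(start = BiocGenerics::start(gaps), end = BiocGenerics::end(gaps))
    }
    bind_rows(
      if (nrow(isl)) isl |> mutate(region = "island") |> select("start", "end", "region"),
      ldr |> mutate(region = "ldr")
    ) |> mutate(scaffold = sc)
  }) |> bind_rows()

  # TE copies: fill each region to its target density with non-overlapping
  # copies so the realised union fraction tracks the nominal density
  sf_tab <- params$superfamilies
  te <- purrr::pmap(regions, function(start, end, region, scaffold) {
    rho <- params$te_density[[region]]
    if (rho == 0) return(NULL)
    rl <- end - start + 1
    target <- rho * rl
    mean_len <- exp(params$te_len_meanlog[[region]] + params$te_len_sdlog^2 / 2)
    n <- max(0L, as.integer(round(target / mean_len)))
    if (n == 0) return(NULL)
    lens <- pmax(50L, as.integer(round(stats::rlnorm(
      n, params$te_len_meanlog[[region]], params$te_len_sdlog
    ))))
    # rescale so the drawn copies occupy the target bp
    lens <- pmax(50L, as.integer(round(lens * target / sum(lens))))
    while (sum(lens) > rl) lens <- lens[-length(lens)]
    if (length(lens) == 0) return(NULL)
    w <- sf_tab$weight * (if (region == "island") sf_tab$island_bias else 1)
    fam <- sample(nrow(sf_tab), length(lens), replace = TRUE, prob = w)
    s <- place_blocks(lens, rl) + start - 1L
    tibble(
      scaffold = scaffold, start = s, end = s + lens - 1L,
      strand = sample(c("+", "-"), length(lens), replace = TRUE),
      kind = "te_copy",
      id = NA_character_, parent = NA_character_,
      te_class = sf_tab$te_class[fam],
      superfamily = sf_tab$superfamily[fam],
      phase = NA_integer_
    )
  }) |> purrr::compact() |> bind_rows()
  if (nrow(te) > 0) {
    te <- te |> mutate(id = sprintf("te%05d", row_number()))
  } else {
    te <- feature_tibble_empty()
  }

  # genes: sampled placements avoiding >= 50% TE overlap and other genes
  clip_bp <- function(s, e, iv_s, iv_e) {
    if (length(iv_s) == 0) return(0L)
    sum(pmax(0L, pmin(e, iv_e) - pmax(s, iv_s) + 1L))
  }
  genes <- list()
  gi <- 0L
  for (sc in sc_ids) {
    te_sc <- te |> filter(.data$scaffold == sc)
    te_red <- merge_intervals(te_sc$start, te_sc$end)
    occupied <- list(start = integer(), end = integer())
    write_pos <- vector("list", 0)
    write_chr <- vector("list", 0)
    n_target <- as.integer(round(L / 1000 * params$gene_per_kb))
    for (k in seq_len(n_target)) {
      n_ex <- sample(params$n_exons[1]:params$n_exons[2], 1)
      codons <- sample(params$exon_codons[1]:params$exon_codons[2], n_ex,
                       replace = TRUE)
      ex_len <- codons * 3L
      introns <- if (n_ex > 1) {
        sample(params$intron_len[1]:params$intron_len[2], n_ex - 1,
               replace = TRUE)
      } else {
        integer()
      }
      foot <- sum(ex_len) + sum(introns)
      placed <- FALSE
      for (try in 1:20) {
        s <- sample.int(L - foot, 1)
        e <- s + foot - 1L
        ov_te <- clip_bp(s, e, te_red$start, te_red$end)
        ov_gene <- clip_bp(s, e, occupied$start, occupied$end)
        if (ov_te < 0.5 * foot && ov_gene == 0) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      gi <- gi + 1L
      occupied$start <- c(occupied$start, s)
      occupied$end <- c(occupied$end, e)
      ex_start <- s + c(0L, cumsum(ex_len[-n_ex] + introns))
      ex_end <- ex_start + ex_len - 1L
      strand <- sample(c("+", "-"), 1)
      mid <- (s + e) %/% 2
      isl <- truth_islands |> filter(.data$scaffold == sc)
      region <- if (nrow(isl) > 0 && any(mid >= isl$start & mid <= isl$end)) "island" else "ldr"
      latent <- rnorm(1)
      p_conv <- if (region == "island") {
        params$cpg_conversion_max[["island"]] * (1 - stats::pnorm(latent))
      } else {
        params$cpg_conversion_max[["ldr"]] * stats::pnorm(latent)
      }
      orf <- deplete_cpg(random_orf(sum(codons)), p_conv)
      genomic <- if (strand == "-") revcomp_chr(orf) else orf
      # queue the exon chunks; all writes are applied to the scaffold in
      # one batch below (repeated full-vector copies are the bottleneck)
      write_pos[[length(write_pos) + 1L]] <- unlist(
        purrr::map2(ex_start, ex_end, seq), use.names = FALSE
      )
      write_chr[[length(write_chr) + 1L]] <- strsplit(genomic, "")[[1]]
      gene_id <- sprintf("g%04d", gi)
      # CDS phase in translation order
      tx_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      phase <- integer(n_ex)
      cum <- 0L
      for (j in tx_order) {
        phase[j] <- (3L - cum %% 3L) %% 3L
        cum <- cum + ex_len[j]
      }
      genes[[gi]] <- list(sc = sc, s = s, e = e, strand = strand,
                          gene_id = gene_id, ex_start = ex_start,
                          ex_end = ex_end, phase = phase, region = region,
                          latent = latent, p_conv = p_conv)
    }
    if (length(write_pos) > 0) {
      x <- seqs[[sc]]
      x[unlist(write_pos, use.names = FALSE)] <- unlist(write_chr,
                                                        use.names = FALSE)
      seqs[[sc]] <- x
    }
  }
  # assemble gene/exon/CDS feature rows in one pass
  gv <- function(f, how = vapply, what = character(1)) how(genes, f, what)
  n_ex_all <- vapply(genes, function(g) length(g$ex_start), integer(1))
  gene_rows <- tibble(
    scaffold = gv(function(g) g$sc), start = gv(function(g) g$s, what = integer(1)),
    end = gv(function(g) g$e, what = integer(1)),
    strand = gv(function(g) g$strand), kind = "gene",
    id = gv(function(g) g$gene_id), parent = NA_character_,
    te_class = NA_character_, superfamily = NA_character_,
    phase = NA_integer_
  )
  child_rows <- function(kind, suffix, with_phase) {
    tibble(
      scaffold = rep(gene_rows$scaffold, n_ex_all),
      start = unlist(lapply(genes, function(g) g$ex_start), use.names = FALSE),
      end = unlist(lapply(genes, function(g) g$ex_end), use.names = FALSE),
      strand = rep(gene_rows$strand, n_ex_all),
      kind = kind,
      id = unlist(lapply(genes, function(g) {
        paste0(g$gene_id, suffix, seq_along(g$ex_start))
      }), use.names = FALSE),
      parent = rep(gene_rows$id, n_ex_all),
      te_class = NA_character_, superfamily = NA_character_,
      phase = if (with_phase) {
        unlist(lapply(genes, function(g) g$phase), use.names = FALSE)
      } else {
        NA_integer_
      }
    )
  }
  feat_genes <- if (length(genes) == 0) {
    gene_rows
  } else {
    bind_rows(gene_rows, child_rows("exon", ".e", FALSE),
              child_rows("cds", ".c", TRUE))
  }
  truth_genes <- tibble(
    gene_id = gene_rows$id, scaffold = gene_rows$scaffold,
    start = gene_rows$start, end = gene_rows$end, strand = gene_rows$strand,
    region = gv(function(g) g$region),
    latent = gv(function(g) g$latent, what = numeric(1)),
    cpg_conversion = gv(function(g) g$p_conv, what = numeric(1))
  )

  # collapsed duplications inside islands
  dups <- if (params$n_duplications > 0 && nrow(truth_islands) > 0) {
    per_isl <- sample(rep(seq_len(nrow(truth_islands)),
                          length.out = params$n_duplications))
    purrr::map(seq_len(nrow(truth_islands)), function(i) {
      n <- sum(per_isl == i)
      if (n == 0) return(NULL)
      isl <- truth_islands[i, ]
      dl <- as.integer(params$duplication_len)
      s <- place_blocks(rep(dl, n), isl$end - isl$start + 1L) + isl$start - 1L
      tibble(scaffold = isl$scaffold, start = s, end = s + dl - 1L,
             lineage = sample(params$lineages, n, replace = TRUE))
    }) |> purrr::compact() |> bind_rows()
  } else {
    tibble(scaffold = character(), start = integer(), end = integer(),
           lineage = character())
  }
  if (nrow(dups) > 0) {
    dups <- dups |>
      arrange(.data$scaffold, .data$start) |>
      mutate(dup_id = paste0("dup_", row_number()))
  }

  scaffolds <- tibble(
    scaffold = sc_ids,
    length = L,
    sequence = unname(vapply(seqs, paste, character(1), collapse = ""))
  )
  features <- bind_rows(te, feat_genes) |>
    arrange(.data$scaffold, .data$start, .data$end)
  list(
    scaffolds = scaffolds,
    features = features,
    truth = list(islands = truth_islands, duplications = dups,
                 genes = truth_genes, params = params)
  )
}

#' Simulate pooled per-base read depth for two lineages
#'
#' Per-base depth is Poisson around the nominal depth, modulated by a
#' lineage-independent 1 kb-block lognormal mappability factor whose spread
#' is larger inside islands (multi-mapping noise around repeats), and
#' doubled across each planted duplication in that duplication's lineage
#' (the collapsed-assembly signature).
#'
#' @param genome Output of [simulate_genome()].
#' @param params The same [sim_params()] list.
#' @return A named list (one per lineage) of depth tibbles with columns
#'   `lineage`, `scaffold`, `pos`, `depth`.
#' @export
simulate_coverage <- function(genome, params = genome$truth$params) {
  set.seed(params$seed + 1L)
  truth <- genome$truth
  out <- list()
  for (l in params$lineages) {
    pieces <- purrr::map(genome$scaffolds$scaffold, function(sc) {
      L <- genome$scaffolds$length[genome$scaffolds$scaffold == sc]
      n_block <- ceiling(L / 1000)
      block_region <- rep("ldr", n_block)
      isl <- truth$islands |> filter(.data$scaffold == sc)
      if (nrow(isl) > 0) {
        mids <- (seq_len(n_block) - 1) * 1000 + 500
        for (i in seq_len(nrow(isl))) {
          block_region[mids >= isl$start[i] & mids <= isl$end[i]] <- "island"
        }
      }
      sd_block <- unname(params$ratio_noise_sd[block_region])
      noise <- exp(rnorm(n_block, 0, sd_block))
      lambda <- params$depth * rep(noise, each = 1000)[seq_len(L)]
      dup <- truth$duplications |>
        filter(.data$scaffold == sc, .data$lineage == l)
      if (nrow(dup) > 0) {
        for (i in seq_len(nrow(dup))) {
          lambda[dup$start[i]:dup$end[i]] <- 2 * lambda[dup$start[i]:dup$end[i]]
        }
      }
      tibble(lineage = l, scaffold = sc, pos = seq_len(L),
             depth = rpois(L, lambda))
    })
    out[[l]] <- bind_rows(pieces)
  }
  out
}

#' Simulate SNV calls with planted structure
#'
#' Homozygous divergence SNVs are placed at region-specific per-kb rates
#' (hom_alt in one random lineage), rare true heterozygous calls at low
#' background rates, and dense spurious heterozygous calls inside each
#' planted duplication (het in the duplication's lineage). Per-lineage
#' depths are taken from the coverage tracks when given, otherwise drawn
#' from the same model.
#'
#' @param genome Output of [simulate_genome()].
#' @param params The same [sim_params()] list.
#' @param coverage Optional output of [simulate_coverage()].
#' @return A list: `snvs` (long tibble as from [read_snv_vcf()]) and
#'   `truth` (tibble `scaffold`, `pos`, `true_class` in
#'   `divergence`/`true_het`/`collapsed_duplication`, `region`).
#' @export
simulate_snvs <- function(genome, params = genome$truth$params,
                          coverage = NULL) {
  set.seed(params$seed + 2L)
  truth <- genome$truth
  regions <- purrr::map(genome$scaffolds$scaffold, function(sc) {
    L <- genome$scaffolds$length[genome$scaffolds$scaffold == sc]
    isl <- truth$islands |> filter(.data$scaffold == sc)
    if (nrow(isl) == 0) {
      return(tibble(scaffold = sc, start = 1L, end = as.integer(L), region = "ldr"))
    }
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(L)),
                             IRanges::IRanges(isl$start, isl$end))
    bind_rows(
      tibble(scaffold = sc, start = isl$start, end = isl$end, region = "island"),
      tibble(scaffold = sc, start = BiocGenerics::start(gaps),
             end = BiocGenerics::end(gaps), region = "ldr")
    )
  }) |> bind_rows()

  draw_sites <- function(start, end, rate_per_kb) {
    n <- rpois(1, (end - start + 1) / 1000 * rate_per_kb)
    if (n == 0) return(integer())
    sort(sample(start:end, min(n, end - start + 1)))
  }
  seqs <- setNames(genome$scaffolds$sequence, genome$scaffolds$scaffold)

  site_rows <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    hom <- draw_sites(rg$start, rg$end, params$hom_snv_per_kb[[rg$region]])
    het <- draw_sites(rg$start, rg$end, params$het_snv_per_kb[[rg$region]])
    site_rows[[i]] <- bind_rows(
      if (length(hom)) tibble(scaffold = rg$scaffold, pos = hom,
                              true_class = "divergence", region = rg$region,
                              carrier = sample(params$lineages, length(hom),
                                               replace = TRUE)),
      if (length(het)) tibble(scaffold = rg$scaffold, pos = het,
                              true_class = "true_het", region = rg$region,
                              carrier = sample(params$lineages, length(het),
                                               replace = TRUE))
    )
  }
  dup_rows <- purrr::map(seq_len(nrow(truth$duplications)), function(i) {
    d <- truth$duplications[i, ]
    pos <- draw_sites(d$start, d$end, params$dup_het_per_kb)
    if (length(pos) == 0) return(NULL)
    tibble(scaffold = d$scaffold, pos = pos,
           true_class = "collapsed_duplication", region = "island",
           carrier = d$lineage)
  }) |> purrr::compact()
  sites <- bind_rows(c(site_rows, dup_rows))
  if (nrow(sites) > 0) {
    sites <- sites |>
      distinct(.data$scaffold, .data$pos, .keep_all = TRUE) |>
      arrange(.data$scaffold, .data$pos)
  } else {
    sites <- tibble(scaffold = character(), pos = integer(),
                    true_class = character(), region = character(),
                    carrier = character())
  }
  if (nrow(sites) == 0) {
    empty <- tibble(scaffold = character(), pos = integer(), ref = character(),
                    alt = character(), lineage = character(),
                    zygosity = character(), depth = integer())
    return(list(snvs = empty, truth = sites))
  }

  sites$ref <- stringr::str_sub(seqs[sites$scaffold], sites$pos, sites$pos)
  alt_pool <- c("A", "C", "G", "T")
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(alt_pool, r), 1),
                      character(1))

  depth_at <- function(lineage, scaffold, pos) {
    if (!is.null(coverage)) {
      cv <- coverage[[lineage]]
      out <- integer(length(pos))
      for (sc in unique(scaffold)) {
        rows <- cv$scaffold == sc
        sel <- scaffold == sc
        out[sel] <- as.integer(cv$depth[rows][match(pos[sel], cv$pos[rows])])
      }
      return(out)
    }
    dup <- truth$duplications |> filter(.data$lineage == !!lineage)
    in_dup <- rep(FALSE, length(pos))
    if (nrow(dup) > 0) {
      for (i in seq_len(nrow(dup))) {
        in_dup <- in_dup | (scaffold == dup$scaffold[i] &
                              pos >= dup$start[i] & pos <= dup$end[i])
      }
    }
    rpois(length(pos), params$depth * ifelse(in_dup, 2, 1))
  }

  snvs <- purrr::map(params$lineages, function(l) {
    zyg <- dplyr::case_when(
      sites$true_class == "divergence" & sites$carrier == l ~ "hom_alt",
      sites$true_class %in% c("true_het", "collapsed_duplication") &
        sites$carrier == l ~ "het",
      TRUE ~ "hom_ref"
    )
    tibble(scaffold = sites$scaffold, pos = sites$pos, ref = sites$ref,
           alt = sites$alt, lineage = l, zygosity = zyg,
           depth = depth_at(l, sites$scaffold, sites$pos))
  }) |> bind_rows() |> arrange(.data$scaffold, .data$pos, .data$lineage)

  list(snvs = snvs,
       truth = sites |> select("scaffold", "pos", "true_class", "region"))
}

#' Simulate a gene x sample count table
#'
#' Negative-binomial counts per gene and sample. Gene means follow a
#' lognormal driven by the gene's latent expression score; island gene
#' means are multiplied by the down-factor, and additionally by the group
#' effect in queen samples (island genes are relatively more expressed in
#' adults). Dispersion 0 falls back to Poisson.
#'
#' @param genome Output of [simulate_genome()].
#' @param params The same [sim_params()] list.
#' @return A list: `counts` (tibble `gene_id` + one column per sample) and
#'   `groups` (named character vector sample -> group).
#' @export
simulate_counts <- function(genome, params = genome$truth$params) {
  set.seed(params$seed + 3L)
  g <- genome$truth$genes
  samples <- c(sprintf("queen%02d", seq_len(params$n_queens)),
               sprintf("larva%02d", seq_len(params$n_larvae)))
  groups <- setNames(rep(c("queen", "larva"), c(params$n_queens, params$n_larvae)),
                     samples)
  mu_gene <- params$expr_base_mean * exp(params$expr_sdlog * g$latent) *
    ifelse(g$region == "island", params$expr_island_down, 1)
  counts <- matrix(0L, nrow = nrow(g), ncol = length(samples),
                   dimnames = list(g$gene_id, samples))
  for (s in samples) {
    mu <- mu_gene * ifelse(g$region == "island" & groups[[s]] == "queen",
                           params$expr_island_group_effect, 1)
    counts[, s] <- if (params$expr_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / params$expr_dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }
  list(counts = bind_cols(tibble(gene_id = g$gene_id), as_tibble(counts)),
       groups = groups)
}

#' Substitute homozygous SNVs into a scaffold sequence
#'
#' Builds a lineage consensus: positions where the lineage is `hom_alt` get
#' the alternate allele; heterozygous and missing positions keep the
#' reference base.
#'
#' @param scaffolds Scaffold tibble with sequences.
#' @param snvs Long SNV tibble.
#' @param lineage Lineage whose consensus to build.
#' @return `scaffolds` with substituted sequences.
#' @export
substitute_snvs <- function(scaffolds, snvs, lineage) {
  s <- snvs |>
    filter(.data$lineage == !!lineage, .data$zygosity == "hom_alt")
  out <- scaffolds
  for (i in seq_len(nrow(out))) {
    si <- s |> filter(.data$scaffold == out$scaffold[i])
    if (nrow(si) == 0) next
    x <- strsplit(out$sequence[i], "")[[1]]
    x[si$pos] <- si$alt
    out$sequence[i] <- paste(x, collapse = "")
  }
  out
}
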