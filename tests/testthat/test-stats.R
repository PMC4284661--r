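# From-scratch enumeration of the two-sided Fisher p for a 2x2 table, via
# log-binomial coefficients (independent of dhyper).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- logp[xs == a]
  sum(exp(logp)[exp(logp) <= exp(p_obs) * (1 + 1e-7)])
}

test_that("two-sided Fisher p follows the probability-mass rule", {
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5))$p_value, 1)
  res <- fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  zero <- fisher_exact_two_sided(c(0, 0, 3, 7))
  expect_equal(zero$p_value, 1)
  expect_true(zero$degenerate)
})

test_that("Fisher p and odds ratio agree with stats::fisher.test", {
  set.seed(99)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    mine <- fisher_exact_two_sided(tab)
    ref <- stats::fisher.test(tab)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    if (!mine$degenerate && is.finite(mine$odds_ratio) && mine$odds_ratio > 0) {
      # fisher.test finds its MLE root at ~1e-4 tolerance
      expect_equal(mine$odds_ratio, unname(ref$estimate), tolerance = 1e-3)
    }
  }
})

test_that("Fisher p matches full enumeration for all small tables", {
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(
        fisher_exact_two_sided(c(a, b, cc, d), odds_ratio = FALSE)$p_value,
        enum_fisher_p(a, b, cc, d),
        tolerance = 1e-12
      )
    }
  }
})

test_that("BH step-up matches hand-computed q-values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(c(0.05, 0.01)), c(0.05, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("removing smaller p-values never decreases a retained q", {
  set.seed(7)
  for (rep in 1:20) {
    p <- sort(runif(15))
    q_full <- bh_fdr(p)
    i <- sample(3:15, 1)
    drop <- sample(seq_len(i - 1), sample(i - 1, 1))
    keep <- setdiff(seq_along(p), drop)
    q_sub <- bh_fdr(p[keep])
    expect_true(q_sub[keep == i] >= q_full[i] - 1e-12)
  }
})

test_that("Mann-Whitney U: exact small-sample and degenerate behaviour", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  # identical multisets: fully tied, p = 1
  expect_equal(mann_whitney_u(c(1, 1, 2), c(1, 2, 1))$p_value, 1)
  # clear shift detected by the normal approximation
  big <- mann_whitney_u(1:50 + 20 + runif(50) * 1e-9, 1:50 + runif(50) * 1e-9)
  expect_lt(big$p_value, 0.001)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney U matches brute-force enumeration at tiny n", {
  # all C(8,4) labelings of 8 distinct values
  set.seed(31)
  vals <- sort(runif(8))
  combos <- utils::combn(8, 4)
  for (rep in 1:5) {
    pick <- combos[, sample(ncol(combos), 1)]
    x <- vals[pick]; y <- vals[-pick]
    u_obs <- sum(rank(c(x, y))[1:4]) - 4 * 5 / 2
    us <- apply(combos, 2, function(ix) {
      sum(rank(c(vals[ix], vals[-ix]))[1:4]) - 10
    })
    mu <- 4 * 4 / 2
    p_enum <- mean(abs(us - mu) >= abs(u_obs - mu))
    expect_equal(mann_whitney_u(x, y)$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact Mann-Whitney p at n = 15", {
  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15, mean = runif(1, 0, 1.5))
    exact <- mann_whitney_u(x, y)
    expect_equal(exact$method, "exact")
    # force the approximation path by inflating n with distinct padding
    u <- exact$u
    mu <- 15 * 15 / 2
    sig2 <- 15 * 15 * 31 / 12
    p_norm <- min(1, 2 * pnorm((abs(u - mu) - 0.5) / sqrt(sig2),
                               lower.tail = FALSE))
    expect_lt(abs(p_norm - exact$p_value), 0.01)
  }
})

test_that("superfamily tallies split copies and bp at island boundaries", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1000L,
                                       end = 2000L), c(s1 = 10000))
  f <- dplyr::bind_rows(
    te_row("s1", 1100, 1200, "Gypsy"),          # inside
    te_row("s1", 1300, 1400, "Gypsy"),          # inside
    te_row("s1", 1500, 1600, "Gypsy"),          # inside
    te_row("s1", 1901, 2100, "hAT", "II"),      # straddles; midpoint 2000 inside
    te_row("s1", 5000, 5100, "hAT", "II"),
    te_row("s1", 6000, 6100, NA_character_)     # unclassified
  )
  tal <- tally_superfamilies(f, part)
  gy <- tal[tal$superfamily == "Gypsy", ]
  expect_equal(gy$copies_islands, 3)
  expect_equal(gy$copies_ldr, 0)
  ha <- tal[tal$superfamily == "hAT", ]
  expect_equal(ha$copies_islands, 1)   # midpoint rule
  expect_equal(ha$copies_ldr, 1)
  expect_equal(ha$bp_islands, 100)     # 1901..2000 inside
  expect_equal(ha$bp_ldr, 100 + 101)   # 2001..2100 plus the LDR copy
  expect_true("unclassified" %in% tal$superfamily)

  # empty partition: everything is LDR-side
  none <- toy_partition(tibble::tibble(scaffold = character(),
                                       start = integer(), end = integer()),
                        c(s1 = 10000))
  tal0 <- tally_superfamilies(f, none)
  expect_true(all(tal0$copies_islands == 0))
})

test_that("superfamily enrichment flags a strongly island-biased family", {
  tal <- tibble::tibble(
    superfamily = c("biased", "bgA", "bgB"),
    te_class = "I",
    copies_islands = c(50L, 3L, 2L),
    copies_ldr = c(50L, 47L, 48L),
    bp_islands = c(50000, 3000, 2000),
    bp_ldr = c(50000, 47000, 48000)
  )
  enr <- superfamily_enrichment(tal)
  hit <- enr[enr$analysis == "copies" & enr$unit == "biased", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "over")

  flat <- tibble::tibble(
    superfamily = c("a", "b", "c"), te_class = "I",
    copies_islands = c(10L, 20L, 30L), copies_ldr = c(100L, 200L, 300L),
    bp_islands = c(1e4, 2e4, 3e4), bp_ldr = c(1e5, 2e5, 3e5)
  )
  expect_false(any(superfamily_enrichment(flat)$significant))

  single <- tal[1, ]
  expect_warning(res <- superfamily_enrichment(single), "degenerate")
  expect_equal(nrow(res), 0)
})

test_that("TE length polymorphism compares island vs LDR per class", {
  part <- toy_partition(tibble::tibble(scaffold = "s1", start = 1L,
                                       end = 10000L), c(s1 = 1e6))
  f <- dplyr::bind_rows(
    te_row("s1", 1000, 1899, "Gypsy"),         # island, length 900
    te_row("s1", 3000, 3999, "Gypsy"),         # island, length 1000
    te_row("s1", 50000, 50299, "Gypsy"),       # LDR, length 300
    te_row("s1", 60000, 60399, "Gypsy")        # LDR, length 400
  )
  lp <- length_polymorphism(f, part)
  expect_equal(lp$median_islands[lp$te_class == "I"], 950)
  expect_equal(lp$median_ldr[lp$te_class == "I"], 350)
  expect_false(lp$skipped[lp$te_class == "I"])
  expect_false("II" %in% lp$te_class)  # class II absent entirely

  # class with too few copies in one compartment is flagged skipped
  f2 <- dplyr::bind_rows(f, te_row("s1", 2000, 2100, "hAT", "II"))
  lp2 <- length_polymorphism(f2, part)
  expect_true(lp2$skipped[lp2$te_class == "II"])
})

test_that("two-tailed term enrichment reports both directions", {
  set.seed(1)
  universe <- paste0("g", 1:110)
  island <- paste0("g", 1:10)
  terms <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:10), term = "island_term"),
    tibble::tibble(gene_id = paste0("g", 11:20), term = "island_term"),
    tibble::tibble(gene_id = paste0("g", 11:60), term = "ldr_term"),
    tibble::tibble(gene_id = paste0("g", sample(1:110, 20)), term = "flat")
  )
  res <- term_enrichment_two_tailed(terms, island, universe)
  it <- res[res$unit == "island_term", ]
  expect_true(it$significant)
  expect_equal(it$direction, "over")
  lt <- res[res$unit == "ldr_term", ]
  expect_equal(lt$direction, "under")
  expect_equal(nrow(term_enrichment_two_tailed(
    tibble::tibble(gene_id = character(), term = character()),
    island, universe
  )), 0)
  expect_error(term_enrichment_two_tailed(terms, c("gX"), universe))
})
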