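hit_tbl <- function(starts, ends, marker = "m1", chrom = "c1", class = "RFLP",
                    evalue = 0) {
  tibble::tibble(marker_id = marker, marker_class = class, chrom = chrom,
                 start = starts, end = ends, evalue = evalue)
}

test_that("RFLP assembly merges hits within 5 kb and splits beyond", {
  h <- hit_tbl(c(100, 3000, 9000), c(300, 3200, 9200))
  loci <- assemble_rflp_loci(h)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$start, c(100, 9000))
  expect_equal(loci$end, c(3200, 9200))
  expect_equal(loci$n_support_hits, c(2L, 1L))

  one <- assemble_rflp_loci(hit_tbl(500, 700))
  expect_equal(one[, c("start", "end")], tibble::tibble(start = 500, end = 700))

  two_chr <- dplyr::bind_rows(hit_tbl(100, 200, chrom = "c1"),
                              hit_tbl(150, 250, chrom = "c2"))
  expect_equal(nrow(assemble_rflp_loci(two_chr)), 2)
})

test_that("assembly is invariant under input permutation and matches the
           single-linkage oracle", {
  withr::local_seed(202)
  for (trial in 1:20) {
    n <- sample(2:12, 1)
    h <- random_hit_tibble(n, max_pos = 5e4, width = sample(20:200, 1))
    loci <- assemble_rflp_loci(h)
    shuffled <- assemble_rflp_loci(h[sample.int(n), ])
    expect_equal(as.data.frame(loci), as.data.frame(shuffled))

    want <- oracle_single_linkage(h$start, h$end, dist = 5000)
    expect_equal(loci$start, unname(want[, "start"]))
    expect_equal(loci$end, unname(want[, "end"]))
  }
})

ssr_hits <- function(plus_starts, minus_starts, width = 20, marker = "s1",
                     plus_class = "SSR_FWD", minus_class = "SSR_REV") {
  dplyr::bind_rows(
    tibble::tibble(marker_id = marker, marker_class = plus_class, chrom = "c1",
                   start = plus_starts, end = plus_starts + width - 1,
                   strand = "+", evalue = 0),
    tibble::tibble(marker_id = marker, marker_class = minus_class, chrom = "c1",
                   start = minus_starts, end = minus_starts + width - 1,
                   strand = "-", evalue = 0)
  )
}

test_that("primer pairing requires convergent orientation within 1 kb", {
  paired <- pair_primer_hits(ssr_hits(500, 880))
  expect_equal(nrow(paired), 1)
  expect_equal(paired$start, 500)
  expect_equal(paired$end, 899)
  expect_equal(paired$n_support_hits, 2L)

  expect_equal(nrow(pair_primer_hits(ssr_hits(500, 2000))), 0)

  # same strand on both hits: not convergent
  same <- ssr_hits(500, 880)
  same$strand <- "+"
  expect_equal(nrow(pair_primer_hits(same)), 0)

  # two disjoint convergent pairs: both recovered, no hit reused
  two <- pair_primer_hits(ssr_hits(c(500, 5000), c(880, 5400)))
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(500, 5000))
  expect_equal(two$end, c(899, 5419))
})

test_that("greedy pairing matches the transparent nearest-first scan", {
  withr::local_seed(303)
  for (trial in 1:20) {
    np <- sample(1:4, 1); nm <- sample(1:4, 1)
    h <- ssr_hits(sample.int(5000, np), sample.int(5000, nm))
    got <- pair_primer_hits(h)
    want <- oracle_pair_scan(as.data.frame(h), max_dist = 1000)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

locus_tbl <- function(starts, ends, class = "SSR", marker = "m1") {
  tibble::tibble(marker_id = marker, marker_class = class, chrom = "c1",
                 start = starts, end = ends, n_support_hits = 1L, evalue_sum = 0)
}

test_that("dedup collapses clustered copies to the leftmost representative", {
  # two SSR loci 800 bp apart: collapsed
  d <- dedup_loci(locus_tbl(c(1000, 1900), c(1099, 1999)))
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 1000)

  # 5 kb apart: both kept (SSR rule is 1 kb)
  expect_equal(nrow(dedup_loci(locus_tbl(c(1000, 6100), c(1099, 6199)))), 2)

  # RFLP 4 kb apart: collapsed (5 kb rule)
  expect_equal(nrow(dedup_loci(locus_tbl(c(1000, 5100), c(1099, 5199),
                                         class = "RFLP"))), 1)

  # chains collapse transitively to one
  chain <- dedup_loci(locus_tbl(c(1000, 1900, 2800), c(1099, 1999, 2899)))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$start, 1000)
})

test_that("dedup agrees with the brute-force chain-collapse oracle", {
  withr::local_seed(404)
  for (trial in 1:20) {
    n <- sample(2:10, 1)
    s <- sample.int(2e4, n)
    l <- locus_tbl(s, s + 99)
    d <- dedup_loci(l)
    comp <- oracle_single_linkage(l$start, l$end, dist = 1000)
    expect_equal(nrow(d), nrow(comp))
  }
})

test_that("copy numbers are capped by smallest summed E-value with the
           zero-loci side list kept apart", {
  loci <- locus_tbl(seq(1000, 61000, by = 10000), seq(1099, 61099, by = 10000))
  loci$evalue_sum <- c(5, 1, 2, 3, 4, 6, 7) * 1e-20
  res <- copy_number_table(loci, all_marker_ids = c("m1", "m_absent"), cap = 5)
  expect_equal(res$totals$n_loci, 5)
  expect_equal(sort(res$loci$evalue_sum), sort(c(1, 2, 3, 4, 5) * 1e-20))
  expect_equal(res$unmapped_markers, "m_absent")
  expect_equal(res$summary$n_loci, res$summary$copy_class * res$summary$n_markers)
})

test_that("copy summary percentages and identities hold on mixed panels", {
  copies <- c(rep(1L, 10), rep(2L, 5), rep(3L, 5))
  s <- copy_summary_from_counts(copies)
  expect_equal(s$summary$n_markers, c(10L, 5L, 5L))
  expect_equal(s$summary$n_loci, c(10L, 10L, 15L))
  expect_equal(sum(s$summary$pct_markers), 100, tolerance = 0.05)
  expect_equal(sum(s$summary$pct_loci), 100, tolerance = 0.05)
  expect_equal(s$mean_copies, round(35 / 20, 2))
  expect_equal(glance(s)$n_loci, 35)
  expect_equal(tidy(s), s$summary)
})
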