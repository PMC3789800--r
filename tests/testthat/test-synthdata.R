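test_that("generation is deterministic and produces the configured shape", {
  cfg <- tiny_config(seed = 3L)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$genetic_map, b2$genetic_map)
  expect_identical(b1$truth$marker_copies, b2$truth$marker_copies)
  expect_identical(b1$qtl, b2$qtl)

  expect_equal(length(b1$genome), 2L)
  expect_equal(unname(Biostrings::width(b1$genome)), rep(2e6, 2))

  genes <- b1$genes
  by_chr <- split(genes, genes$chrom)
  for (g in by_chr) {
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))  # non-overlapping
    expect_identical(g$order_rank, seq_len(nrow(g)))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(copy_number_weights = c(0.5, 0.4)), "sum to 1")
  expect_error(synth_config(chrom_length_bp = 100), "10 x")
  expect_error(
    synth_config(inversions = data.frame(chrom = c(1L, 1L),
                                         start = c(1e6, 2e6), end = c(3e6, 4e6))),
    "disjoint")
  expect_error(
    synth_config(inversions = data.frame(chrom = 1L, start = 1e6, end = 99e6)),
    "within")
})

test_that("every truth marker copy is recoverable by substring extraction", {
  b <- simulate_bundle(tiny_config(seed = 5L))
  gen <- as.character(b$genome)
  copies <- b$truth$marker_copies
  plen <- b$config$primer_len_bp

  rflp <- copies[copies$marker_class == "RFLP", ]
  for (i in seq_len(nrow(rflp))) {
    found <- substr(gen[[rflp$chrom[i]]], rflp$start[i], rflp$end[i])
    want <- as.character(b$rflp[[rflp$marker_id[i]]])
    if (rflp$strand[i] == "-") {
      want <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(want)))
    }
    expect_identical(found, want)
  }

  ssr <- copies[copies$marker_class == "SSR", ]
  expect_true(all(ssr$end - ssr$start + 1 == b$config$amplicon_bp))
  for (i in seq_len(min(nrow(ssr), 50))) {
    row <- b$ssr_primers[b$ssr_primers$marker_id == ssr$marker_id[i], ]
    fwd_site <- substr(gen[[ssr$chrom[i]]], ssr$start[i], ssr$start[i] + plen - 1)
    rev_site <- substr(gen[[ssr$chrom[i]]], ssr$end[i] - plen + 1, ssr$end[i])
    expect_identical(fwd_site, row$fwd_seq)
    expect_identical(
      rev_site,
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(row$rev_seq))))
  }
})

test_that("decoy markers are planted nowhere", {
  b <- simulate_bundle(tiny_config(seed = 5L))
  decoys <- b$markers$marker_id[b$markers$decoy]
  expect_gt(length(decoys), 0)
  expect_false(any(b$truth$marker_copies$marker_id %in% decoys))
})

test_that("empirical copy-number distribution matches the weights", {
  b <- default_bundle()
  planted <- b$markers[!b$markers$decoy, ]
  expect_gte(nrow(planted), 1900)
  w <- b$config$copy_number_weights
  n <- nrow(planted)
  for (k in seq_along(w)) {
    p_hat <- mean(planted$copies == k)
    se <- sqrt(w[k] * (1 - w[k]) / n)
    expect_lt(abs(p_hat - w[k]), 3 * se)
  }
})

test_that("planted inversions reverse physical order along the map", {
  b <- simulate_bundle(tiny_config(seed = 5L))
  inv <- b$config$inversions
  copies <- b$truth$marker_copies
  mp <- b$genetic_map |>
    dplyr::inner_join(copies, by = "marker_id") |>
    dplyr::filter(.data$chrom == "Chr01",
                  .data$start >= inv$start[1], .data$start <= inv$end[1]) |>
    dplyr::arrange(.data$position_cM)
  expect_gte(nrow(mp), 3)
  expect_true(all(diff(mp$start) < 0))
})

test_that("translocated markers carry the acceptor map chromosome", {
  cfg <- tiny_config(seed = 9L,
                     inversions = no_rearrangements()$inversions,
                     translocations = data.frame(donor = 1L, acceptor = 2L,
                                                 start = 2e5, end = 9e5))
  b <- simulate_bundle(cfg)
  tr <- b$truth$rearrangements
  expect_identical(tr$kind, "translocation")
  ids <- tr$marker_ids[[1]]
  expect_gt(length(ids), 0)
  rows <- b$genetic_map[b$genetic_map$marker_id %in% ids, ]
  expect_true(all(rows$map_chrom == "Chr02"))
  phys <- b$truth$marker_copies[b$truth$marker_copies$marker_id %in% ids, ]
  expect_true(all(phys$chrom == "Chr01"))
})

test_that("undetectably small inversions trigger a warning", {
  cfg <- tiny_config(seed = 13L,
                     inversions = data.frame(chrom = 1L, start = 1e5, end = 1.1e5))
  expect_warning(simulate_bundle(cfg), "undetectable")
})

test_that("hotspot QTL have distinct trait codes within the window", {
  b <- simulate_bundle(tiny_config(seed = 5L))
  hs <- b$truth$qtl_hotspots
  for (i in seq_len(nrow(hs))) {
    q <- b$qtl[b$qtl$name %in% hs$qtl_names[[i]], ]
    expect_equal(nrow(q), hs$n_traits[i])
    expect_equal(dplyr::n_distinct(q$trait), hs$n_traits[i])
    expect_true(all(abs(q$peak_cM - hs$center_cM[i]) <=
                      b$config$hotspot_window_cm / 2 + 1e-9))
    expect_true(all(q$trait %in% c("EL", "FC", "FF", "FL", "FS", "FU", "MIC", "SF")))
  }
})

test_that("a study without QTL yields an empty QTL table", {
  cfg <- tiny_config(seed = 5L, n_qtl = 0L, hotspot_spec = no_hotspots())
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$qtl), 0)
  expect_named(b$qtl, c("name", "trait", "map_chrom", "peak_cM"))
})
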