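dh <- function(protein, acc, s, e, ev) {
  tibble::tibble(protein_id = protein, accession = acc,
                 env_start = s, env_end = e, evalue = ev)
}

test_that("overlap-dominated domain hits are abandoned", {
  hits <- dplyr::bind_rows(
    dh("g1", "PF00931", 100, 250, 1e-30),
    dh("g1", "PF00069", 200, 400, 1e-50)   # stronger, overlapping: NBS is false
  )
  kept <- filter_domain_hits(hits)
  expect_false("PF00931" %in% kept$accession)

  hits2 <- dplyr::bind_rows(
    dh("g1", "PF00931", 100, 250, 1e-30),
    dh("g1", "PF00069", 200, 400, 1e-10)   # weaker: NBS survives
  )
  expect_true("PF00931" %in% filter_domain_hits(hits2)$accession)

  # above the candidate cutoff: dropped regardless
  expect_equal(nrow(filter_domain_hits(dh("g1", "PF00931", 1, 10, 2),
                                       evalue_cutoff = 1)), 0)
})

test_that("overlap filtering equals the all-pairs oracle", {
  withr::local_seed(333)
  accs <- c("PF00931", "PF01582", "PF13855", "PF00069", "PF99999")
  for (trial in 1:20) {
    n <- sample(2:10, 1)
    s <- sample.int(500, n)
    hits <- dh("g1", sample(accs, n, TRUE), s, s + sample.int(200, n),
               10^-runif(n, 0, 40))
    got <- filter_domain_hits(hits)
    want <- oracle_overlap_filter(as.data.frame(hits), cutoff = 1)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$evalue, want$evalue)
  }
})

test_that("RGA classes follow domain architecture with TIR precedence", {
  full <- dplyr::bind_rows(
    dh("g1", "PF01582", 10, 120, 1e-20),
    dh("g1", "PF00931", 150, 450, 1e-30),
    dh("g1", "PF13855", 480, 620, 1e-8)
  )
  expect_equal(classify_rga(full)$rga_class, "TIR-NBS-LRR")

  cc <- dh("g2", "PF00931", 120, 400, 1e-30)
  coils <- tibble::tibble(protein_id = "g2", start = 5L, end = 40L)
  expect_equal(classify_rga(cc, coils)$rga_class, "CC-NBS")

  # no NBS: not an RGA at all
  no_nbs <- dplyr::bind_rows(dh("g3", "PF01582", 10, 120, 1e-20),
                             dh("g3", "PF13855", 480, 620, 1e-8))
  expect_equal(nrow(classify_rga(no_nbs)), 0)

  # TIR beats CC when both present
  both <- dplyr::bind_rows(dh("g4", "PF01582", 100, 200, 1e-20),
                           dh("g4", "PF00931", 250, 500, 1e-30))
  coils4 <- tibble::tibble(protein_id = "g4", start = 5L, end = 60L)
  expect_equal(classify_rga(both, coils4)$rga_class, "TIR-NBS")

  # a coil overlapping a validated domain does not count as CC
  lapped <- dh("g5", "PF00931", 30, 400, 1e-30)
  coils5 <- tibble::tibble(protein_id = "g5", start = 5L, end = 40L)
  expect_equal(classify_rga(lapped, coils5)$rga_class, "NBS")
})

gene_run <- function(flags, chrom = "c1") {
  n <- length(flags)
  tibble::tibble(gene_id = sprintf("%s.g%02d", chrom, 1:n), chrom = chrom,
                 start = 1:n * 10000, end = 1:n * 10000 + 3000,
                 order_rank = 1:n, flag = flags)
}

test_that("clusters are maximal all-RGA runs of at least two genes", {
  g <- gene_run(c(0, 1, 1, 1, 0, 1, 0))
  rga <- tibble::tibble(gene_id = g$gene_id[g$flag == 1], rga_class = "NBS")
  cl <- find_rga_clusters(g, rga)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_rga, 3L)
  expect_equal(cl$gene_ids[[1]], g$gene_id[2:4])

  g2 <- gene_run(c(1, 1, 0, 0))
  cl2 <- find_rga_clusters(g2, tibble::tibble(gene_id = g2$gene_id[1:2],
                                              rga_class = "NBS"))
  expect_equal(cl2$n_rga, 2L)

  g3 <- gene_run(c(0, 0, 0))
  expect_equal(nrow(find_rga_clusters(g3, tibble::tibble(
    gene_id = character(), rga_class = character()))), 0)
})

test_that("no gene belongs to two clusters", {
  withr::local_seed(444)
  for (trial in 1:20) {
    flags <- sample(0:1, 30, TRUE)
    g <- gene_run(flags)
    cl <- find_rga_clusters(g, tibble::tibble(gene_id = g$gene_id[flags == 1],
                                              rga_class = "NBS"))
    members <- unlist(cl$gene_ids)
    expect_equal(anyDuplicated(members), 0)
  }
})

test_that("flanking markers are the nearest loci outside the cluster", {
  cl <- tibble::tibble(cluster_id = "RGC001", chrom = "c1",
                       start = 10000, end = 20000, n_rga = 2L,
                       gene_ids = list(c("a", "b")), classes = list(c("NBS", "NBS")))
  loci <- tibble::tibble(
    chrom = "c1", start = c(9000, 12000, 21000), end = c(9500, 12100, 21400),
    marker_id = c("left", "inside", "right"), marker_class = "RFLP")
  out <- cluster_flanking_markers(cl, loci)
  expect_equal(out$flank_left_marker, "left")
  expect_equal(out$flank_right_marker, "right")
  expect_equal(out$n_internal_markers, 1L)

  # cluster at chromosome start: sentinel flank
  cl0 <- cl; cl0$start <- 1; cl0$end <- 5000
  out0 <- cluster_flanking_markers(cl0, loci)
  expect_equal(out0$flank_left_marker, "chromosome_end")
})
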