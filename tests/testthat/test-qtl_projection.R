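anchor_set <- function(cm, bp, chrom = "c1", map_chrom = "L1") {
  tibble::tibble(chrom = chrom, bp = bp, cM = cm,
                 marker_id = sprintf("a%02d", seq_along(cm)),
                 map_chrom = map_chrom)
}

qtl_tbl <- function(peaks, trait = "FL", map_chrom = "L1") {
  tibble::tibble(name = sprintf("q%02d", seq_along(peaks)), trait = trait,
                 map_chrom = map_chrom, peak_cM = peaks)
}

test_that("QTL project to the nearest straddling anchor pair", {
  a <- anchor_set(c(10, 20), c(1e6, 2e6))
  p <- project_qtl(qtl_tbl(15), a)
  expect_equal(p$bp_start, 1e6)
  expect_equal(p$bp_end, 2e6)
  expect_false(p$clamped)

  # peak exactly at an interior anchor: widened to distinct neighbours
  a3 <- anchor_set(c(10, 20, 30), c(1e6, 2e6, 3e6))
  p2 <- project_qtl(qtl_tbl(20), a3)
  expect_equal(c(p2$bp_start, p2$bp_end), c(1e6, 3e6))

  # peak outside the anchored range: clamped to the terminal pair
  p3 <- project_qtl(qtl_tbl(35), a3)
  expect_true(p3$clamped)
  expect_equal(c(p3$bp_start, p3$bp_end), c(2e6, 3e6))

  expect_error(project_qtl(qtl_tbl(5), anchor_set(10, 1e6)), "anchor")
})

test_that("projection matches brute-force nearest-straddling search", {
  withr::local_seed(555)
  for (trial in 1:5) {
    n <- sample(5:15, 1)
    a <- anchor_set(sort(runif(n, 0, 100)), sort(sample.int(1e7, n)))
    peaks <- runif(30, min(a$cM) + 0.01, max(a$cM) - 0.01)
    p <- project_qtl(qtl_tbl(peaks), a)
    for (k in seq_len(30)) {
      lo <- which(a$cM <= peaks[k]); hi <- which(a$cM >= peaks[k])
      i1 <- max(lo); i2 <- min(hi)
      if (i1 == i2) { i1 <- max(i1 - 1, 1); i2 <- min(i2 + 1, n) }
      expect_equal(p$bp_start[k], min(a$bp[c(i1, i2)]))
      expect_equal(p$bp_end[k], max(a$bp[c(i1, i2)]))
    }
  }
})

test_that("marker counts inside projected intervals use whole containment", {
  a <- anchor_set(c(10, 20), c(1e6, 2e6))
  loci <- tibble::tibble(chrom = "c1",
                         start = c(1.2e6, 0.9e6, 1.99e6), end = c(1.2e6 + 50, 0.95e6, 2.1e6),
                         marker_id = c("in", "before", "straddle"),
                         marker_class = "RFLP")
  p <- project_qtl(qtl_tbl(12), a, loci = loci)
  expect_equal(p$n_markers_in_interval, 1L)
})

test_that("hotspots need at least three distinct traits over overlapping
           intervals", {
  a <- anchor_set(c(10, 20), c(1e6, 2e6))
  q <- qtl_tbl(c(12, 14, 16, 18), trait = "FL")
  q$trait <- c("FL", "FF", "FU", "MIC")
  hs <- find_hotspots(project_qtl(q, a))
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_distinct_traits, 4L)
  expect_equal(hs$n_qtl, 4L)

  q_same <- qtl_tbl(c(12, 14, 16, 18), trait = "FL")
  expect_equal(nrow(find_hotspots(project_qtl(q_same, a))), 0)
})

test_that("hotspot grouping equals overlap-graph connected components", {
  withr::local_seed(666)
  for (trial in 1:30) {
    n <- sample(3:12, 1)
    s <- sample.int(1e6, n)
    proj <- tibble::tibble(
      name = sprintf("q%02d", 1:n), trait = sample(c("FL", "FF", "FU"), n, TRUE),
      map_chrom = "L1", peak_cM = runif(n), phys_chrom = "c1",
      bp_start = s, bp_end = s + sample.int(2e5, n),
      left_marker = "x", right_marker = "y", clamped = FALSE
    )
    groups <- find_hotspots(proj, min_traits = 1)
    comp <- oracle_overlap_components(proj$bp_start, proj$bp_end)
    expect_equal(nrow(groups), length(unique(comp)))
    expect_equal(sort(groups$n_qtl), sort(unname(as.integer(table(comp)))))
  }
})

test_that("scattered single-trait QTL never form a hotspot", {
  withr::local_seed(777)
  a <- anchor_set(sort(runif(20, 0, 100)), sort(sample.int(1e7, 20)))
  for (trial in 1:100) {
    q <- qtl_tbl(runif(sample(2:8, 1), 1, 99), trait = "FS")
    expect_equal(nrow(find_hotspots(project_qtl(q, a))), 0)
  }
})
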