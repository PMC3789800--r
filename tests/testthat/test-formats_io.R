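blast_row <- function(q, s, sstart, send, evalue = 1e-20) {
  paste(q, s, 100, abs(send - sstart) + 1, 0, 0, 1, abs(send - sstart) + 1,
        sstart, send, evalue, 100, sep = "\t")
}

test_that("BLAST tabular hits are parsed with strand normalization", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_row("m1", "c1", 900, 500),
               blast_row("m2", "c1", 100, 250, evalue = "3e-20")), f)
  h <- read_blast_hits(f)
  expect_equal(h$subject_start[1], 500)
  expect_equal(h$subject_end[1], 900)
  expect_equal(h$strand, c("-", "+"))
  expect_equal(h$evalue[2], 3e-20)
})

test_that("empty and malformed hit files are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_equal(nrow(read_blast_hits(f)), 0)

  writeLines(c(blast_row("m1", "c1", 1, 50),
               paste("m2", "c1", 100, 50, 0, 0, 1, 50, "abc", 200, 1e-5, 99,
                     sep = "\t")), f)
  expect_error(read_blast_hits(f), "line 2")
})

test_that("hit writer round-trips through the reader, minus strand included", {
  withr::local_seed(1)
  h <- tibble::tibble(
    query_id = sprintf("m%d", 1:20), subject_id = "c1",
    percent_identity = 100, align_len = 50L,
    subject_start = sample.int(1e5, 20), strand = sample(c("+", "-"), 20, TRUE),
    evalue = runif(20) * 1e-10
  )
  h$subject_end <- h$subject_start + 49L
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(h, f)
  back <- read_blast_hits(f)
  expect_equal(back[, names(h)], h)
})

test_that("genetic map reader validates entries", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(marker_id = c("a", "b", "c"),
                                  map_chrom = "Chr01",
                                  position_cM = c(0, 5.5, 12)), f)
  expect_equal(nrow(read_genetic_map(f)), 3)

  readr::write_tsv(tibble::tibble(marker_id = c("a", "a"), map_chrom = "Chr01",
                                  position_cM = c(0, 1)), f)
  expect_error(read_genetic_map(f), "duplicate")

  readr::write_tsv(tibble::tibble(marker_id = "a", map_chrom = "Chr01",
                                  position_cM = -1), f)
  expect_error(read_genetic_map(f), ">= 0")
})

test_that("the WGMM table round-trips and uses BED coordinates on disk", {
  withr::local_seed(2)
  loci <- tibble::tibble(
    chrom = sample(c("Chr01", "Chr02"), 1000, TRUE),
    start = as.numeric(sample.int(1e6, 1000)),
    marker_id = sprintf("m%04d", 1:1000),
    marker_class = sample(c("RFLP", "SSR"), 1000, TRUE),
    cM = runif(1000, 0, 50),
    anchor = sample(c("anchor", "interpolated", "extrapolated"), 1000, TRUE)
  )
  loci$end <- loci$start + 99
  loci <- loci[order(loci$chrom, loci$start, loci$end, loci$marker_id), ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_wgmm(loci, f)
  back <- read_wgmm(f)
  expect_equal(back[, names(loci)], loci)

  raw <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(raw$start, loci$start - 1)  # 0-based half-open on disk

  one <- loci[1, ]
  one$start <- 101; one$end <- 200
  write_wgmm(one, f)
  expect_equal(readr::read_tsv(f, show_col_types = FALSE)$start, 100)

  write_wgmm(loci[0, ], f)
  expect_equal(nrow(read_wgmm(f)), 0)
  expect_named(read_wgmm(f),
               c("chrom", "start", "end", "marker_id", "marker_class", "cM", "anchor"))
})

test_that("QTL reader rejects unknown trait codes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = "q1", trait = "XX",
                                  map_chrom = "Chr01", peak_cM = 5), f)
  expect_error(read_qtl_table(f), "unknown trait")
})

test_that("a bundle written to disk feeds the file-based pipeline identically", {
  b <- simulate_bundle(tiny_config(seed = 21L))
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))

  genes_back <- read_gene_annotation(paths[["genes"]])
  expect_equal(genes_back[, c("gene_id", "chrom", "start", "end")],
               b$genes[, c("gene_id", "chrom", "start", "end")])

  gm_back <- read_genetic_map(paths[["genetic_map"]])
  expect_equal(as.data.frame(gm_back), as.data.frame(b$genetic_map))

  out <- withr::local_tempdir()
  rep_file <- run_pipeline(
    genome_fa = paths[["genome"]], rflp_fa = paths[["rflp"]],
    ssr_primers_tsv = paths[["ssr_primers"]],
    genetic_map_tsv = paths[["genetic_map"]], genes_gff3 = paths[["genes"]],
    domain_hits_tsv = paths[["domain_hits"]], coils_tsv = paths[["coils"]],
    qtl_tsv = paths[["qtl"]], out_dir = out)
  rep_mem <- run_wgmm(genome = b$genome, rflp = b$rflp,
                      ssr_primers = b$ssr_primers, genetic_map = b$genetic_map,
                      genes = b$genes, domain_hits = b$domain_hits,
                      coils = b$coils, qtl = b$qtl)
  expect_equal(as.data.frame(rep_file$loci), as.data.frame(rep_mem$loci))
  expect_equal(glance(rep_file), glance(rep_mem))
  expect_true(file.exists(file.path(out, "wgmm.bed.tsv")))
  expect_true(file.exists(file.path(out, "run_report.json")))
})
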