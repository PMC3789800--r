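#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses tab-separated alignment records in the standard 12-column BLAST
#' tabular dialect (`qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore`). Subject coordinates are normalized on
#' read: a record with `sstart > send` encodes a minus-strand alignment (the
#' BLAST convention); after reading, `subject_start <= subject_end` always
#' holds and the strand is stored separately. Row order is preserved.
#'
#' @param path Path to the tab-separated file (no header).
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_len`, `subject_start`, `subject_end`,
#'   `strand`, `evalue`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "align_len",
            "mismatch", "gapopen", "query_start", "query_end",
            "subject_start", "subject_end", "evalue", "bitscore")
  raw <- readr::read_tsv(path, col_names = cols,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), align_len = integer(),
                  subject_start = numeric(), subject_end = numeric(),
                  strand = character(), evalue = numeric()))
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at line %d of %s",
                    col, bad[1], path))
    }
    x
  }
  s <- num("subject_start"); e <- num("subject_end"); ev <- num("evalue")
  if (any(ev < 0, na.rm = TRUE)) abort("negative E-value in hit file.")
  if (any(pmin(s, e) < 1, na.rm = TRUE)) abort("subject coordinates must be >= 1.")
  tibble(
    query_id = raw$query_id, subject_id = raw$subject_id,
    percent_identity = num("percent_identity"),
    align_len = as.integer(num("align_len")),
    subject_start = pmin(s, e), subject_end = pmax(s, e),
    strand = ifelse(s > e, "-", "+"), evalue = ev
  )
}

#' Write alignment hits in BLAST tabular dialect
#'
#' Inverse of [read_blast_hits()]: minus-strand records are written with
#' `sstart > send` so the file is bit-compatible with real BLAST output.
#' Columns absent from the in-memory record (mismatches, gap opens, query
#' coordinates, bit score) are written as zeros.
#'
#' @param hits Tibble as returned by [read_blast_hits()] or
#'   [locate_markers()] (a `marker_id`/`chrom`/`start`/`end` layout is also
#'   accepted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  h <- hits
  if ("marker_id" %in% names(h)) {
    h <- h |> rename(query_id = "marker_id", subject_id = "chrom",
                     subject_start = "start", subject_end = "end")
  }
  minus <- h$strand == "-"
  out <- tibble(
    qseqid = h$query_id, sseqid = h$subject_id,
    pident = if ("percent_identity" %in% names(h)) h$percent_identity else 100,
    length = if ("align_len" %in% names(h)) h$align_len else
      as.integer(h$subject_end - h$subject_start + 1),
    mismatch = 0L, gapopen = 0L, qstart = 0L, qend = 0L,
    sstart = ifelse(minus, h$subject_end, h$subject_start),
    send = ifelse(minus, h$subject_start, h$subject_end),
    evalue = h$evalue, bitscore = 0
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genetic map table
#'
#' Expects a tab-separated file with header columns `marker_id`,
#' `map_chrom`, `position_cM`. Validates that cM positions are finite and
#' non-negative and that no (marker, chromosome) pair is duplicated.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `marker_id`, `map_chrom`, `position_cM`.
#' @export
read_genetic_map <- function(path) {
  gm <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), map_chrom = readr::col_character(),
    position_cM = readr::col_double()
  ), progress = FALSE)
  if (any(!is.finite(gm$position_cM)) || any(gm$position_cM < 0)) {
    abort("genetic map cM positions must be finite and >= 0.")
  }
  dup <- gm |> count(.data$marker_id, .data$map_chrom) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate genetic map entry: %s on %s",
                  dup$marker_id[1], dup$map_chrom[1]))
  }
  gm
}

#' @rdname read_genetic_map
#' @param map Genetic map tibble.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(map[, c("marker_id", "map_chrom", "position_cM")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write / read the whole-genome marker map as a BED-like table
#'
#' The WGMM is serialized as a tab-separated table with header columns
#' `chrom`, `start`, `end`, `marker_id`, `class`, `cM`, `anchor_flag`,
#' sorted by chromosome then start. The file surface follows BED
#' conventions: `start` is 0-based and the interval is half-open, while all
#' in-memory coordinates in this package are 1-based fully closed. The pair
#' round-trips losslessly.
#'
#' @param loci Anchored locus tibble (columns `chrom`, `start`, `end`,
#'   `marker_id`, `marker_class`, `cM`, `anchor`).
#' @param path Output path.
#' @return `path` invisibly; `read_wgmm()` returns the locus tibble with
#'   1-based closed coordinates.
#' @export
write_wgmm <- function(loci, path) {
  out <- loci |>
    arrange(.data$chrom, .data$start, .data$end, .data$marker_id) |>
    mutate(start = .data$start - 1) |>
    select("chrom", "start", "end", "marker_id", class = "marker_class",
           cM = "cM", anchor_flag = "anchor")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_wgmm
#' @export
read_wgmm <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), marker_id = readr::col_character(),
    class = readr::col_character(), cM = readr::col_double(),
    anchor_flag = readr::col_character()
  ), progress = FALSE) |>
    mutate(start = .data$start + 1) |>
    rename(marker_class = "class", anchor = "anchor_flag")
}

#' Read simple TSV inputs: SSR primers, domain hits, coils, QTL
#'
#' Each reader validates its header and numeric columns. Formats:
#' `read_ssr_primers`: `marker_id`, `fwd_seq`, `rev_seq`.
#' `read_domain_hits`: `protein_id`, `accession`, `env_start`, `env_end`,
#' `evalue` (a simplified `hmmsearch --domtblout` projection).
#' `read_coils`: `protein_id`, `start`, `end` (coiled-coil segments).
#' `read_qtl_table`: `name`, `trait`, `map_chrom`, `peak_cM`.
#'
#' @param path Path to the TSV (with header).
#' @return A tibble with the columns listed above.
#' @export
read_ssr_primers <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), fwd_seq = readr::col_character(),
    rev_seq = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_ssr_primers
#' @export
read_domain_hits <- function(path) {
  h <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(), accession = readr::col_character(),
    env_start = readr::col_integer(), env_end = readr::col_integer(),
    evalue = readr::col_double()
  ), progress = FALSE)
  if (any(h$env_end < h$env_start) || any(h$evalue < 0)) {
    abort("invalid domain hit: envelope end before start or negative E-value.")
  }
  h
}

#' @rdname read_ssr_primers
#' @export
read_coils <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname read_ssr_primers
#' @export
read_qtl_table <- function(path) {
  q <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), trait = readr::col_character(),
    map_chrom = readr::col_character(), peak_cM = readr::col_double()
  ), progress = FALSE)
  bad <- setdiff(unique(q$trait), FIBER_TRAITS)
  if (length(bad)) {
    abort(sprintf("unknown trait code(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(FIBER_TRAITS, collapse = ", ")))
  }
  q
}

#' Read / write a gene annotation (GFF3, gene features only)
#'
#' Uses rtracklayer for the GFF3 surface. Only rows with `type == "gene"`
#' are kept; `order_rank` is the 1-based index of the gene along its
#' chromosome in physical order.
#'
#' @param path GFF3 path.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `order_rank`.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read GFF3 annotations.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(order_rank = row_number()) |>
    ungroup()
}

#' @rdname read_gene_annotation
#' @param genes Gene tibble (as from [generate_genome()]).
#' @export
write_gene_annotation <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to write GFF3 annotations.")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "wgmm"
  gr$ID <- genes$gene_id
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Serializes every component of a [simulate_bundle()] result: genome and
#' RFLP probes as FASTA, genes as GFF3, SSR primers / genetic map / domain
#' hits / coils / QTL as TSV, and the truth table and configuration as
#' JSON. Re-running with the same bundle gives byte-identical files.
#'
#' @param bundle A `wgmm_bundle`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  Biostrings::writeXStringSet(bundle$rflp, p("markers_rflp.fa"))
  write_gene_annotation(bundle$genes, p("genes.gff3"))
  readr::write_tsv(bundle$ssr_primers, p("ssr_primers.tsv"), progress = FALSE)
  write_genetic_map(bundle$genetic_map, p("genetic_map.tsv"))
  readr::write_tsv(bundle$domain_hits, p("domain_hits.tsv"), progress = FALSE)
  readr::write_tsv(bundle$coils, p("coils.tsv"), progress = FALSE)
  readr::write_tsv(bundle$qtl, p("qtl.tsv"), progress = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(genome = p("genome.fa"), rflp = p("markers_rflp.fa"),
             genes = p("genes.gff3"), ssr_primers = p("ssr_primers.tsv"),
             genetic_map = p("genetic_map.tsv"), domain_hits = p("domain_hits.tsv"),
             coils = p("coils.tsv"), qtl = p("qtl.tsv"),
             truth = p("truth.json"), config = p("config.json"))
  invisible(paths)
}
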