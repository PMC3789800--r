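#' Pipeline parameter set
#'
#' Collects every numeric threshold of the marker-map pipeline with its
#' default: E-value bounds of 1e-10 (sequences) and 50 (primers), RFLP hit
#' merge distance 5000 bp, primer pairing distance 1000 bp, duplicate-copy
#' collapse distances of 1000 bp (SSR) and 5000 bp (RFLP), 1-Mb density
#' windows at 100-kb steps, inversion reporting above 1 Mb with at least 3
#' markers, a 10-cM discrepancy cutoff, domain-search E-value cutoff 1,
#' hotspot minimum of 3 distinct traits, and a copy-number cap of 5.
#'
#' @param evalue_sequence,evalue_primer See [filter_thresholds()].
#' @param rflp_merge_bp RFLP hit merge distance (bp).
#' @param primer_pair_bp Maximum primer pairing distance (bp).
#' @param ssr_dedup_bp,rflp_dedup_bp Duplicate-copy collapse distances (bp).
#' @param window_bp,step_bp Density window and step (bp).
#' @param inv_min_span_mb,inv_min_markers Inversion reporting thresholds.
#' @param max_cm_offset Discrepant-locus cutoff (cM).
#' @param hmm_evalue Domain hit E-value cutoff.
#' @param hotspot_min_traits Minimum distinct traits per hotspot.
#' @param copy_cap Copy-number ceiling.
#' @return A named list of class `wgmm_params`.
#' @export
pipeline_config <- function(evalue_sequence = 1e-10, evalue_primer = 50,
                            rflp_merge_bp = 5000, primer_pair_bp = 1000,
                            ssr_dedup_bp = 1000, rflp_dedup_bp = 5000,
                            window_bp = 1e6, step_bp = 1e5,
                            inv_min_span_mb = 1, inv_min_markers = 3,
                            max_cm_offset = 10, hmm_evalue = 1,
                            hotspot_min_traits = 3, copy_cap = 5) {
  p <- list(evalue_sequence = evalue_sequence, evalue_primer = evalue_primer,
            rflp_merge_bp = rflp_merge_bp, primer_pair_bp = primer_pair_bp,
            ssr_dedup_bp = ssr_dedup_bp, rflp_dedup_bp = rflp_dedup_bp,
            window_bp = window_bp, step_bp = step_bp,
            inv_min_span_mb = inv_min_span_mb, inv_min_markers = inv_min_markers,
            max_cm_offset = max_cm_offset, hmm_evalue = hmm_evalue,
            hotspot_min_traits = hotspot_min_traits, copy_cap = copy_cap)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all pipeline distances, windows and cutoffs must be positive.")
  }
  structure(p, class = "wgmm_params")
}

#' Run the whole marker-map pipeline in memory
#'
#' Executes every stage in order on in-memory inputs: exact marker
#' location (or externally supplied hits), E-value filtering, locus
#' assembly and primer pairing, duplicate-copy removal, copy-number
#' accounting, colinearity anchoring with cM interpolation and discrepancy
#' removal, density statistics, inversion/translocation detection, RGA
#' cluster identification, and QTL projection with hotspot grouping.
#' Stages whose inputs are absent are skipped and noted in the report.
#'
#' @param genome Named [Biostrings::DNAStringSet] (required unless `hits`
#'   is supplied together with `chrom_lengths`).
#' @param rflp,ssr_primers Marker panel (see [locate_markers()]); either
#'   may be `NULL`.
#' @param hits Optional pre-computed hit tibble (e.g. from
#'   [read_blast_hits()], relabelled with `marker_id`/`marker_class`);
#'   when given, exact matching is skipped.
#' @param genetic_map,genes,domain_hits,coils,qtl Optional stage inputs.
#' @param chrom_lengths Named lengths (bp); derived from `genome` when
#'   absent.
#' @param assembled_bp,total_bp Coverage numerator/denominator; default to
#'   the summed chromosome lengths.
#' @param params A [pipeline_config()].
#' @return A list of class `wgmm_report`; see [tidy.wgmm_report()].
#' @export
run_wgmm <- function(genome = NULL, rflp = NULL, ssr_primers = NULL,
                     hits = NULL, genetic_map = NULL, genes = NULL,
                     domain_hits = NULL, coils = NULL, qtl = NULL,
                     chrom_lengths = NULL, assembled_bp = NULL,
                     total_bp = NULL, params = pipeline_config()) {
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[stage]] <<- tibble(stage = stage, n_in = n_in, n_out = n_out)
  }

  if (is.null(chrom_lengths)) {
    if (is.null(genome)) abort("need `genome` or `chrom_lengths`.")
    chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  }
  if (is.null(total_bp)) total_bp <- sum(chrom_lengths)
  if (is.null(assembled_bp)) assembled_bp <- sum(chrom_lengths)

  # --- hits ---------------------------------------------------------------
  if (is.null(hits)) {
    if (is.null(genome)) abort("need `genome` to locate markers, or supply `hits`.")
    hits <- locate_markers(genome, rflp = rflp, ssr_primers = ssr_primers)
  }
  n_raw <- nrow(hits)
  hits <- filter_hits(hits, filter_thresholds(params$evalue_sequence,
                                              params$evalue_primer))
  note("filter_hits", n_raw, nrow(hits))

  # --- loci ---------------------------------------------------------------
  rflp_loci <- assemble_rflp_loci(hits[hits$marker_class == "RFLP", ],
                                  merge_dist_bp = params$rflp_merge_bp)
  ssr_loci <- pair_primer_hits(hits[hits$marker_class %in% c("SSR_FWD", "SSR_REV"), ],
                               max_dist_bp = params$primer_pair_bp)
  loci <- bind_rows(rflp_loci, ssr_loci)
  note("assemble_loci", nrow(hits), nrow(loci))
  loci <- dedup_loci(loci, ssr_dist_bp = params$ssr_dedup_bp,
                     rflp_dist_bp = params$rflp_dedup_bp)
  note("dedup_loci", stages$assemble_loci$n_out, nrow(loci))

  all_ids <- unique(c(if (!is.null(rflp)) names(rflp),
                      if (!is.null(ssr_primers)) ssr_primers$marker_id,
                      hits$marker_id))
  copy_summary <- copy_number_table(loci, all_ids, cap = params$copy_cap)
  loci <- copy_summary$loci
  note("copy_cap", stages$dedup_loci$n_out, nrow(loci))

  # --- anchoring ----------------------------------------------------------
  wgmm <- NULL; anchors <- NULL; removed <- NULL; dotpoints <- NULL
  rearrangements <- rearrangement_call_tibble()
  if (!is.null(genetic_map)) {
    dotpoints <- build_dotpoints(loci, genetic_map)
    loci_map <- loci |>
      inner_join(genetic_map, by = c("marker_id", chrom = "map_chrom")) |>
      rename(map_cM = "position_cM") |>
      mutate(map_chrom = .data$chrom)
    anchors <- detect_colinear_anchors(loci_map)
    rem <- remove_discrepant(loci_map, anchors, params$max_cm_offset)
    removed <- rem$removed
    keep_key <- paste(loci$marker_id, loci$chrom, loci$start)
    drop_key <- paste(removed$marker_id, removed$chrom, removed$start)
    loci_kept <- loci[!(keep_key %in% drop_key), ]
    wgmm <- interpolate_cm(loci_kept, anchors)
    note("anchor_interpolate", nrow(loci), nrow(wgmm))

    inv <- detect_inversions(dotpoints, min_span_mb = params$inv_min_span_mb,
                             min_markers = params$inv_min_markers)
    tra <- detect_translocations(dotpoints, min_markers = params$inv_min_markers)
    map_totals <- genetic_map |>
      group_by(.data$map_chrom) |>
      summarise(total = max(.data$position_cM), .groups = "drop")
    rearrangements <- summarize_rearrangement(
      bind_rows(inv, tra),
      chrom_length_mb = setNames(chrom_lengths / 1e6, names(chrom_lengths)),
      map_total_cm = setNames(map_totals$total, map_totals$map_chrom)
    )
    note("rearrangements", nrow(dotpoints), nrow(rearrangements))
  }

  # --- density ------------------------------------------------------------
  density <- density_summary(loci, chrom_lengths,
                             n_genes = if (!is.null(genes)) nrow(genes) else NA_integer_,
                             assembled_bp = assembled_bp, total_bp = total_bp,
                             window_bp = params$window_bp, step_bp = params$step_bp)

  # --- RGA ----------------------------------------------------------------
  rga <- NULL; clusters <- NULL
  if (!is.null(domain_hits) && !is.null(genes)) {
    rga <- classify_rga(domain_hits, coils, evalue_cutoff = params$hmm_evalue)
    clusters <- find_rga_clusters(genes, rga)
    clusters <- cluster_flanking_markers(clusters, loci)
    note("rga_clusters", nrow(rga), nrow(clusters))
  }

  # --- QTL ----------------------------------------------------------------
  projected <- NULL; hotspots <- NULL
  if (!is.null(qtl) && !is.null(anchors) && nrow(qtl) > 0) {
    projected <- project_qtl(qtl, anchors, loci = loci)
    hotspots <- find_hotspots(projected, min_traits = params$hotspot_min_traits)
    note("qtl_hotspots", nrow(qtl), nrow(hotspots))
  }

  structure(list(
    loci = loci, wgmm = wgmm, anchors = anchors, removed = removed,
    copy_summary = copy_summary, density = density,
    dotpoints = dotpoints, rearrangements = rearrangements,
    rga = rga, rga_clusters = clusters,
    projected_qtl = projected, hotspots = hotspots,
    stages = bind_rows(stages), params = params,
    version = as.character(utils::packageVersion("wgmm"))
  ), class = "wgmm_report")
}

#' @export
print.wgmm_report <- function(x, ...) {
  cat("Whole-genome marker map report (wgmm", x$version, ")\n", sep = "")
  cat(" loci:", nrow(x$loci),
      "| anchors:", if (is.null(x$anchors)) 0 else nrow(x$anchors),
      "| rearrangements:", nrow(x$rearrangements),
      "| RGA clusters:", if (is.null(x$rga_clusters)) 0 else nrow(x$rga_clusters),
      "| QTL hotspots:", if (is.null(x$hotspots)) 0 else nrow(x$hotspots), "\n")
  print(x$stages)
  invisible(x)
}

#' Tidy / glance methods for pipeline reports
#'
#' `tidy()` returns the per-stage input/output record counts;
#' `glance()` a one-row summary of the main result sizes.
#'
#' @param x A `wgmm_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wgmm_report <- function(x, ...) x$stages

#' @rdname tidy.wgmm_report
#' @export
glance.wgmm_report <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci),
    n_markers_mapped = x$copy_summary$totals$n_markers,
    mean_copies = x$copy_summary$mean_copies,
    n_anchors = if (is.null(x$anchors)) 0L else nrow(x$anchors),
    n_rearrangements = nrow(x$rearrangements),
    n_rga_clusters = if (is.null(x$rga_clusters)) 0L else nrow(x$rga_clusters),
    n_qtl_hotspots = if (is.null(x$hotspots)) 0L else nrow(x$hotspots),
    mean_kb_per_locus = x$density$genome$mean_kb_per_locus
  )
}

#' Run the pipeline from files on disk
#'
#' Thin file-based wrapper around [run_wgmm()]: reads the inputs with the
#' package readers, runs the pipeline, and writes the standard outputs
#' (WGMM BED-like table, hit table, locus/copy summaries, rearrangement,
#' cluster and hotspot reports, and a JSON run report) into `out_dir`.
#' Re-running with identical inputs gives byte-identical outputs.
#'
#' @param genome_fa Genome FASTA path (required).
#' @param rflp_fa,ssr_primers_tsv,genetic_map_tsv,genes_gff3,
#'   domain_hits_tsv,coils_tsv,qtl_tsv Optional input paths; `NULL` skips
#'   the stage.
#' @param hits_tsv Optional BLAST tabular hits (replaces internal exact
#'   matching; `query_id` must be marker ids, with primer queries suffixed
#'   `/F` or `/R`).
#' @param out_dir Output directory.
#' @param params A [pipeline_config()].
#' @return The `wgmm_report`, invisibly.
#' @export
run_pipeline <- function(genome_fa, rflp_fa = NULL, ssr_primers_tsv = NULL,
                         hits_tsv = NULL, genetic_map_tsv = NULL,
                         genes_gff3 = NULL, domain_hits_tsv = NULL,
                         coils_tsv = NULL, qtl_tsv = NULL,
                         out_dir = "wgmm_out", params = pipeline_config()) {
  genome <- Biostrings::readDNAStringSet(genome_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  rflp <- if (!is.null(rflp_fa)) {
    x <- Biostrings::readDNAStringSet(rflp_fa)
    names(x) <- sub("\\s.*$", "", names(x)); x
  }
  ssr <- if (!is.null(ssr_primers_tsv)) read_ssr_primers(ssr_primers_tsv)
  hits <- if (!is.null(hits_tsv)) {
    h <- read_blast_hits(hits_tsv)
    h |> mutate(
      marker_id = sub("/[FR]$", "", .data$query_id),
      marker_class = dplyr::case_when(
        grepl("/F$", .data$query_id) ~ "SSR_FWD",
        grepl("/R$", .data$query_id) ~ "SSR_REV",
        TRUE ~ "RFLP"
      )
    ) |>
      rename(chrom = "subject_id", start = "subject_start", end = "subject_end")
  }
  gm <- if (!is.null(genetic_map_tsv)) read_genetic_map(genetic_map_tsv)
  genes <- if (!is.null(genes_gff3)) read_gene_annotation(genes_gff3)
  dh <- if (!is.null(domain_hits_tsv)) read_domain_hits(domain_hits_tsv)
  coils <- if (!is.null(coils_tsv)) read_coils(coils_tsv)
  qtl <- if (!is.null(qtl_tsv)) read_qtl_table(qtl_tsv)

  report <- run_wgmm(genome = genome, rflp = rflp, ssr_primers = ssr,
                     hits = hits, genetic_map = gm, genes = genes,
                     domain_hits = dh, coils = coils, qtl = qtl,
                     params = params)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(report$wgmm)) write_wgmm(report$wgmm, p("wgmm.bed.tsv"))
  readr::write_tsv(report$loci, p("loci.tsv"), progress = FALSE)
  readr::write_tsv(report$copy_summary$summary, p("copy_number_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$density$windows, p("window_density.tsv"), progress = FALSE)
  readr::write_tsv(report$rearrangements, p("rearrangements.tsv"), progress = FALSE)
  if (!is.null(report$rga_clusters)) {
    readr::write_tsv(report$rga_clusters |>
                       mutate(gene_ids = purrr::map_chr(.data$gene_ids, paste, collapse = ","),
                              classes = purrr::map_chr(.data$classes, paste, collapse = ",")),
                     p("rga_clusters.tsv"), progress = FALSE)
  }
  if (!is.null(report$hotspots)) {
    readr::write_tsv(report$hotspots |>
                       mutate(qtl_names = purrr::map_chr(.data$qtl_names, paste, collapse = ",")),
                     p("qtl_hotspots.tsv"), progress = FALSE)
  }
  jsonlite::write_json(
    list(stages = report$stages,
         glance = glance(report),
         params = unclass(report$params), version = report$version),
    p("run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Simulate a study and run the pipeline end to end
#'
#' Generates the default synthetic bundle for `seed`, runs the full
#' pipeline on it, prints the copy-number and rearrangement summaries, and
#' returns both the bundle (with its truth table) and the report.
#'
#' @param seed Integer seed for the synthetic study.
#' @param config Optional [synth_config()] overriding the default (its
#'   seed is replaced by `seed`).
#' @param quiet Suppress printing.
#' @return List with `bundle` and `report`, invisibly.
#' @export
make_demo <- function(seed = 42L, config = NULL, quiet = FALSE) {
  cfg <- config %||% synth_config(seed = seed)
  cfg$seed <- as.integer(seed)
  bundle <- simulate_bundle(cfg)
  report <- run_wgmm(
    genome = bundle$genome, rflp = bundle$rflp,
    ssr_primers = bundle$ssr_primers, genetic_map = bundle$genetic_map,
    genes = bundle$genes, domain_hits = bundle$domain_hits,
    coils = bundle$coils, qtl = bundle$qtl
  )
  if (!quiet) {
    print(report)
    print(report$copy_summary)
    print(report$rearrangements)
  }
  invisible(list(bundle = bundle, report = report))
}
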