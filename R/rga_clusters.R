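# Pfam/clan accessions for RGA architecture. The LRR set lists LRR-clan
# (CL0022) family members accepted as evidence of LRR repeats.
NBS_ACCESSION <- "PF00931"
TIR_ACCESSION <- "PF01582"
LRR_ACCESSIONS <- c("PF00560", "PF07723", "PF07725", "PF12799", "PF13306",
                    "PF13516", "PF13855", "PF14580", "PF01463", "PF08263")

#' Filter domain hits by overlap adjudication
#'
#' A candidate hit with E-value at or below `evalue_cutoff` is retained iff
#' no hit of a different domain (different accession) on the same protein
#' overlaps its envelope (at least one shared residue) with a strictly
#' lower E-value. Overlap-dominated hits are false positives of the weaker
#' model and are abandoned.
#'
#' @param hits Domain hit tibble: `protein_id`, `accession`, `env_start`,
#'   `env_end`, `evalue`.
#' @param evalue_cutoff Candidate E-value cutoff (default 1).
#' @return The retained hits.
#' @export
filter_domain_hits <- function(hits, evalue_cutoff = 1) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits |>
    group_by(.data$protein_id) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      ok <- g$evalue <= evalue_cutoff
      for (i in which(ok)) {
        dominated <- g$accession != g$accession[i] &
          g$env_start <= g$env_end[i] & g$env_start[i] <= g$env_end &
          g$evalue < g$evalue[i]
        if (any(dominated)) ok[i] <- FALSE
      }
      g[ok, ]
    })
  bind_rows(keep)
}

#' Classify genes as resistance gene analogs from domain architecture
#'
#' A gene is an RGA iff it carries at least one validated NBS (NB-ARC)
#' domain. The class is assembled from the presence of a validated TIR
#' domain, validated LRR repeats (any LRR-clan family), and an N-terminal
#' coiled-coil segment: one ending before the NBS envelope start and
#' overlapping no validated domain. TIR takes precedence over CC when both
#' are present.
#'
#' @param domain_hits Raw domain hit tibble (filtering is applied
#'   internally via [filter_domain_hits()]).
#' @param coils Coiled-coil segment tibble: `protein_id`, `start`, `end`.
#' @param evalue_cutoff Passed to [filter_domain_hits()].
#' @param lrr_accessions Accessions accepted as LRR evidence.
#' @return Tibble `gene_id`, `rga_class` for RGA genes only. Classes:
#'   TIR-NBS-LRR, TIR-NBS, CC-NBS-LRR, CC-NBS, NBS-LRR, NBS.
#' @export
classify_rga <- function(domain_hits, coils = NULL, evalue_cutoff = 1,
                         lrr_accessions = LRR_ACCESSIONS) {
  valid <- filter_domain_hits(domain_hits, evalue_cutoff)
  if (nrow(valid) == 0) return(tibble(gene_id = character(), rga_class = character()))
  per <- valid |>
    group_by(.data$protein_id) |>
    summarise(
      has_nbs = any(.data$accession == NBS_ACCESSION),
      has_tir = any(.data$accession == TIR_ACCESSION),
      has_lrr = any(.data$accession %in% lrr_accessions),
      nbs_start = suppressWarnings(min(.data$env_start[.data$accession == NBS_ACCESSION])),
      .groups = "drop"
    ) |>
    filter(.data$has_nbs)
  if (nrow(per) == 0) return(tibble(gene_id = character(), rga_class = character()))

  has_cc <- vapply(seq_len(nrow(per)), function(i) {
    if (is.null(coils) || nrow(coils) == 0) return(FALSE)
    cc <- coils[coils$protein_id == per$protein_id[i], ]
    if (nrow(cc) == 0) return(FALSE)
    dom <- valid[valid$protein_id == per$protein_id[i], ]
    any(vapply(seq_len(nrow(cc)), function(k) {
      n_terminal <- cc$end[k] < per$nbs_start[i]
      clash <- any(dom$env_start <= cc$end[k] & cc$start[k] <= dom$env_end)
      n_terminal && !clash
    }, TRUE))
  }, TRUE)

  per |>
    mutate(
      prefix = dplyr::case_when(.data$has_tir ~ "TIR-", has_cc ~ "CC-", TRUE ~ ""),
      suffix = ifelse(.data$has_lrr, "-LRR", ""),
      rga_class = paste0(.data$prefix, "NBS", .data$suffix)
    ) |>
    select(gene_id = "protein_id", "rga_class")
}

#' Find RGA clusters along gene order
#'
#' A cluster is a maximal run of genes at consecutive order ranks that are
#' all RGAs, with at least two members and no intervening non-RGA gene.
#' Singleton RGAs are not clusters. No maximum bp gap is imposed.
#'
#' @param genes Gene tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `order_rank` (consecutive per chromosome).
#' @param rga Tibble `gene_id`, `rga_class` from [classify_rga()].
#' @param min_size Minimum cluster size (default 2).
#' @return Cluster tibble: `cluster_id`, `chrom`, `start`, `end`, `n_rga`,
#'   `gene_ids` (list), `classes` (list).
#' @export
find_rga_clusters <- function(genes, rga, min_size = 2) {
  g <- genes |>
    mutate(is_rga = .data$gene_id %in% rga$gene_id) |>
    arrange(.data$chrom, .data$order_rank)
  out <- g |>
    group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(gc) {
      r <- rle(gc$is_rga)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      purrr::map_dfr(seq_along(r$values), function(k) {
        if (!r$values[k] || r$lengths[k] < min_size) return(NULL)
        idx <- starts[k]:ends[k]
        tibble(
          chrom = gc$chrom[1],
          start = min(gc$start[idx]), end = max(gc$end[idx]),
          n_rga = length(idx), gene_ids = list(gc$gene_id[idx]),
          classes = list(rga$rga_class[match(gc$gene_id[idx], rga$gene_id)])
        )
      })
    })
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_rga = integer(),
                  gene_ids = list(), classes = list()))
  }
  out |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("RGC%03d", row_number())) |>
    relocate("cluster_id")
}

#' Attach flanking marker loci to RGA clusters
#'
#' For each cluster: the left flank is the marker locus with the greatest
#' end before the cluster start, the right flank the locus with the
#' smallest start after the cluster end, and the internal count is the
#' number of loci lying wholly inside the cluster interval. A missing
#' flank (cluster at a chromosome end) is reported as `"chromosome_end"`.
#'
#' @param clusters Cluster tibble from [find_rga_clusters()].
#' @param loci Marker locus tibble (the WGMM).
#' @return The clusters with added `flank_left_marker`,
#'   `flank_right_marker`, `n_internal_markers`.
#' @export
cluster_flanking_markers <- function(clusters, loci) {
  if (nrow(clusters) == 0) {
    return(clusters |> mutate(flank_left_marker = character(),
                              flank_right_marker = character(),
                              n_internal_markers = integer()))
  }
  one <- function(i) {
    cl <- clusters[i, ]
    lc <- loci[loci$chrom == cl$chrom, ]
    left <- lc[lc$end < cl$start, ]
    right <- lc[lc$start > cl$end, ]
    inside <- lc[lc$start >= cl$start & lc$end <= cl$end, ]
    tibble(
      flank_left_marker = if (nrow(left)) left$marker_id[which.max(left$end)] else "chromosome_end",
      flank_right_marker = if (nrow(right)) right$marker_id[which.min(right$start)] else "chromosome_end",
      n_internal_markers = nrow(inside)
    )
  }
  clusters |>
    select(-dplyr::any_of(c("flank_left_marker", "flank_right_marker",
                            "n_internal_markers"))) |>
    dplyr::bind_cols(purrr::map_dfr(seq_len(nrow(clusters)), one))
}
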