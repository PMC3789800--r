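#' Assemble RFLP hits into loci by single-linkage distance clustering
#'
#' Within each (marker, chromosome) group, hits are clustered along the
#' chromosome by single linkage: two hits join one cluster iff the inner
#' gap between their intervals (start of the right hit minus end of the
#' left) is at most `merge_dist_bp`; overlapping hits always merge. Each
#' cluster becomes one locus spanning the minimum start to the maximum end
#' of its hits. The result is invariant under permutation of the input.
#'
#' @param hits Hit tibble (class `RFLP`) with `marker_id`, `chrom`,
#'   `start`, `end`, `evalue`.
#' @param merge_dist_bp Maximum inner gap joining two hits (default 5000).
#' @return Locus tibble: `marker_id`, `marker_class`, `chrom`, `start`,
#'   `end`, `n_support_hits`, `evalue_sum`.
#' @export
assemble_rflp_loci <- function(hits, merge_dist_bp = 5000) {
  if (nrow(hits) == 0) {
    return(tibble(marker_id = character(), marker_class = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  n_support_hits = integer(), evalue_sum = numeric()))
  }
  hits |>
    arrange(.data$marker_id, .data$chrom, .data$start, .data$end) |>
    group_by(.data$marker_id, .data$chrom) |>
    mutate(
      reach = cummax(.data$end),
      new_cluster = .data$start - lag(.data$reach, default = first(.data$start)) > merge_dist_bp,
      cluster = cumsum(.data$new_cluster)
    ) |>
    group_by(.data$marker_id, .data$chrom, .data$cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_support_hits = n(), evalue_sum = sum(.data$evalue),
              .groups = "drop") |>
    mutate(marker_class = "RFLP") |>
    select("marker_id", "marker_class", "chrom", "start", "end",
           "n_support_hits", "evalue_sum")
}

#' Pair forward and reverse SSR primer hits into amplicon loci
#'
#' Candidate pairs are a forward-primer hit and a reverse-primer hit of the
#' same marker on the same chromosome in convergent orientation (the two
#' hits on opposite strands with their 3' ends facing inward, i.e. the
#' plus-strand hit upstream of the minus-strand hit) whose inner distance
#' (start of the downstream hit minus end of the upstream hit) is at most
#' `max_dist_bp`. Pairs are accepted greedily in ascending distance order
#' with deterministic tie-breaking; each hit is used at most once. The
#' locus spans the outermost coordinates of the accepted pair.
#'
#' @param hits Hit tibble with classes `SSR_FWD` and `SSR_REV`.
#' @param max_dist_bp Maximum inner distance between the paired hits
#'   (default 1000).
#' @return Locus tibble as in [assemble_rflp_loci()] with
#'   `marker_class = "SSR"` and `n_support_hits = 2`.
#' @export
pair_primer_hits <- function(hits, max_dist_bp = 1000) {
  empty <- tibble(marker_id = character(), marker_class = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  n_support_hits = integer(), evalue_sum = numeric())
  if (nrow(hits) == 0) return(empty)
  hits <- hits |> mutate(.hit_id = row_number())

  pair_group <- function(g) {
    plus <- g[g$strand == "+", ]
    minus <- g[g$strand == "-", ]
    if (nrow(plus) == 0 || nrow(minus) == 0) return(NULL)
    cand <- tidyr::expand_grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    cand$dist <- minus$start[cand$j] - plus$end[cand$i]
    # convergent: plus-strand hit strictly upstream, one FWD + one REV
    ok <- cand$dist >= 1 & cand$dist <= max_dist_bp &
      plus$marker_class[cand$i] != minus$marker_class[cand$j]
    cand <- cand[ok, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$dist, plus$start[cand$i], minus$start[cand$j]), ]
    used_p <- logical(nrow(plus)); used_m <- logical(nrow(minus))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_p[i] && !used_m[j]) {
        keep[k] <- TRUE; used_p[i] <- TRUE; used_m[j] <- TRUE
      }
    }
    cand <- cand[keep, ]
    tibble(
      marker_id = g$marker_id[1], marker_class = "SSR", chrom = g$chrom[1],
      start = plus$start[cand$i], end = minus$end[cand$j],
      n_support_hits = 2L,
      evalue_sum = plus$evalue[cand$i] + minus$evalue[cand$j]
    )
  }

  hits |>
    group_by(.data$marker_id, .data$chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(pair_group) |>
    (\(x) if (nrow(x) == 0) empty else arrange(x, .data$marker_id, .data$chrom, .data$start))()
}

#' Deduplicate clustered locus copies of one marker
#'
#' Among loci of the same marker on one chromosome, loci whose spans lie
#' within the class-specific distance (inner gap) form single-linkage
#' chains that collapse to the leftmost-starting representative. This
#' removes clustered duplicate copies while leaving well-separated copies
#' (true multi-copy placements) untouched.
#'
#' @param loci Locus tibble (mixed classes allowed).
#' @param ssr_dist_bp Collapse distance for SSR loci (default 1000).
#' @param rflp_dist_bp Collapse distance for RFLP loci (default 5000).
#' @return The deduplicated locus tibble.
#' @export
dedup_loci <- function(loci, ssr_dist_bp = 1000, rflp_dist_bp = 5000) {
  if (nrow(loci) == 0) return(loci)
  loci |>
    mutate(.dist = ifelse(.data$marker_class == "SSR", ssr_dist_bp, rflp_dist_bp)) |>
    arrange(.data$marker_id, .data$marker_class, .data$chrom, .data$start, .data$end) |>
    group_by(.data$marker_id, .data$marker_class, .data$chrom) |>
    mutate(
      reach = cummax(.data$end),
      new_chain = .data$start - lag(.data$reach, default = first(.data$start)) > .data$.dist,
      chain = cumsum(.data$new_chain)
    ) |>
    group_by(.data$marker_id, .data$marker_class, .data$chrom, .data$chain) |>
    # rows are already sorted by (start, end): first row = leftmost
    dplyr::slice_head(n = 1) |>
    ungroup() |>
    select(-".dist", -"reach", -"new_chain", -"chain") |>
    arrange(.data$marker_id, .data$chrom, .data$start)
}

#' Copy-number accounting for mapped markers
#'
#' The copy number of a marker is its deduplicated locus count, truncated
#' at `cap` by retaining the `cap` loci with the smallest summed E-value
#' (ties broken by leftmost coordinate). Markers with zero loci are
#' reported in a side list, not in the summary, so class totals equal
#' mapped markers/loci. For every copy class the identity
#' `n_loci = class x n_markers` holds exactly.
#'
#' @param loci Deduplicated locus tibble.
#' @param all_marker_ids Character vector of every marker searched
#'   (mapped or not).
#' @param cap Copy-number ceiling (default 5).
#' @return A list of class `wgmm_copy_summary`: `summary` (per-class
#'   tibble with `copy_class`, `n_markers`, `pct_markers`, `n_loci`,
#'   `pct_loci`), `totals`, `mean_copies`, `unmapped_markers`, and `loci`
#'   (the retained loci after capping).
#' @export
copy_number_table <- function(loci, all_marker_ids, cap = 5) {
  capped <- loci |>
    group_by(.data$marker_id) |>
    arrange(.data$evalue_sum, .data$chrom, .data$start, .by_group = TRUE) |>
    dplyr::slice_head(n = cap) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
  copies <- capped |> count(.data$marker_id, name = "copies")
  res <- copy_summary_from_counts(copies$copies)
  res$unmapped_markers <- setdiff(all_marker_ids, copies$marker_id)
  res$loci <- capped
  res$copies_per_marker <- copies
  res
}

#' Build the copy-number summary from per-marker copy counts
#'
#' Used by [copy_number_table()] and directly when only the per-class
#' marker counts are known (e.g. reproducing published accounting tables).
#' Percentages are reported to two decimals using largest-remainder
#' rounding, the standard table convention that makes each percentage
#' column total exactly 100.00; the mean copy number is reported to two
#' decimals.
#'
#' @param copies Integer vector: one copy count (>= 1) per mapped marker.
#' @return A list of class `wgmm_copy_summary` (see [copy_number_table()]).
#' @export
copy_summary_from_counts <- function(copies) {
  stopifnot(all(copies >= 1))
  total_markers <- length(copies)
  total_loci <- sum(copies)
  tab <- tibble(copy_class = sort(unique(copies))) |>
    mutate(
      n_markers = vapply(.data$copy_class, function(c) sum(copies == c), 0L),
      pct_markers = pct_largest_remainder(.data$n_markers),
      n_loci = .data$copy_class * .data$n_markers,
      pct_loci = pct_largest_remainder(.data$n_loci)
    )
  structure(
    list(summary = tab,
         totals = tibble(n_markers = total_markers, n_loci = total_loci),
         mean_copies = round2(total_loci / total_markers)),
    class = "wgmm_copy_summary"
  )
}

#' @export
print.wgmm_copy_summary <- function(x, ...) {
  cat("Copy-number summary:", x$totals$n_markers, "markers,",
      x$totals$n_loci, "loci, mean", x$mean_copies, "copies/marker\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wgmm_copy_summary <- function(x, ...) x$summary

#' @export
glance.wgmm_copy_summary <- function(x, ...) {
  tibble(n_markers = x$totals$n_markers, n_loci = x$totals$n_loci,
         mean_copies = x$mean_copies,
         n_unmapped = length(x$unmapped_markers %||% character()))
}
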