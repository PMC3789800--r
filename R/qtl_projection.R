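#' Project QTL peaks onto physical intervals
#'
#' Each QTL peak (a cM position on a map chromosome) is delineated by the
#' two anchor markers nearest to the peak with physical placements: the
#' anchor with the greatest cM at or below the peak and the anchor with the
#' smallest cM at or above it. When the peak coincides exactly with an
#' anchor, the interval is widened to the nearest distinct anchors around
#' it; a peak outside the anchored range is clamped to the terminal anchor
#' pair and flagged. The projected interval is the (ordered) pair of
#' anchor bp positions.
#'
#' @param qtl QTL tibble: `name`, `trait`, `map_chrom`, `peak_cM`.
#' @param anchors Anchor set from [detect_colinear_anchors()] (columns
#'   `chrom`, `bp`, `cM`, `marker_id`, `map_chrom`).
#' @param loci Optional WGMM locus tibble; when given,
#'   `n_markers_in_interval` counts loci lying wholly inside each
#'   projected interval.
#' @return Projected QTL tibble: the QTL columns plus `phys_chrom`,
#'   `bp_start`, `bp_end`, `left_marker`, `right_marker`, `clamped`, and
#'   optionally `n_markers_in_interval`. QTL on map chromosomes without
#'   anchors raise an error.
#' @export
project_qtl <- function(qtl, anchors, loci = NULL) {
  one <- function(i) {
    q <- qtl[i, ]
    a <- anchors[anchors$map_chrom == q$map_chrom, ]
    if (nrow(a) < 2) {
      abort(sprintf("no (or a single) anchor for map chromosome %s: cannot project %s",
                    q$map_chrom, q$name))
    }
    a <- a |> arrange(.data$cM, .data$bp)
    peak <- q$peak_cM
    lo <- which(a$cM <= peak); hi <- which(a$cM >= peak)
    clamped <- FALSE
    if (length(lo) == 0) { i1 <- 1L; i2 <- 2L; clamped <- TRUE }
    else if (length(hi) == 0) { i1 <- nrow(a) - 1L; i2 <- nrow(a); clamped <- TRUE }
    else {
      i1 <- max(lo); i2 <- min(hi)
      if (i1 == i2) {  # peak exactly at an anchor: widen to distinct neighbours
        i1 <- max(i1 - 1L, 1L); i2 <- min(i2 + 1L, nrow(a))
      }
    }
    bp <- sort(c(a$bp[i1], a$bp[i2]))
    dplyr::bind_cols(q, tibble(
      phys_chrom = a$chrom[1], bp_start = bp[1], bp_end = bp[2],
      left_marker = a$marker_id[i1], right_marker = a$marker_id[i2],
      clamped = clamped))
  }
  out <- purrr::map_dfr(seq_len(nrow(qtl)), one)
  if (!is.null(loci) && nrow(out) > 0) {
    out$n_markers_in_interval <- vapply(seq_len(nrow(out)), function(i) {
      sum(loci$chrom == out$phys_chrom[i] & loci$start >= out$bp_start[i] &
            loci$end <= out$bp_end[i])
    }, 0L)
  }
  out
}

#' Group projected QTL into multi-trait hotspots
#'
#' Projected intervals on one physical chromosome are merged by single
#' linkage: two intervals in one group iff they overlap (sharing at least
#' one bp, directly or through a chain). A merged group is a hotspot iff
#' it contains QTL for at least `min_traits` distinct trait codes; the
#' hotspot interval is the union span of its members.
#'
#' @param projected Projected QTL tibble from [project_qtl()].
#' @param min_traits Minimum distinct traits (default 3).
#' @return Hotspot tibble: `phys_chrom`, `bp_start`, `bp_end`, `n_qtl`,
#'   `n_distinct_traits`, `traits` (collapsed string), `qtl_names` (list).
#' @export
find_hotspots <- function(projected, min_traits = 3) {
  empty <- tibble(phys_chrom = character(), bp_start = numeric(),
                  bp_end = numeric(), n_qtl = integer(),
                  n_distinct_traits = integer(), traits = character(),
                  qtl_names = list())
  if (nrow(projected) == 0) return(empty)
  out <- projected |>
    group_by(.data$phys_chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      g <- g |> arrange(.data$bp_start, .data$bp_end)
      reach <- cummax(g$bp_end)
      new_grp <- g$bp_start > dplyr::lag(reach, default = g$bp_start[1])
      g$grp <- cumsum(new_grp)
      g |>
        group_by(.data$grp) |>
        summarise(
          phys_chrom = first(.data$phys_chrom),
          bp_start = min(.data$bp_start), bp_end = max(.data$bp_end),
          n_qtl = n(),
          n_distinct_traits = dplyr::n_distinct(.data$trait),
          traits = paste(sort(unique(.data$trait)), collapse = ";"),
          qtl_names = list(.data$name), .groups = "drop"
        ) |>
        select(-"grp")
    }) |>
    filter(.data$n_distinct_traits >= min_traits)
  if (nrow(out) == 0) empty else arrange(out, .data$phys_chrom, .data$bp_start)
}
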