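#' Build dotplot points from loci and a genetic map
#'
#' One point per (map marker, surviving locus) pair: the marker's genetic
#' position against the physical position of each of its loci. This is the
#' tabular form of a genetic-versus-physical dotplot and the input to
#' inversion and translocation detection.
#'
#' @param loci Locus tibble (`marker_id`, `chrom`, `start`).
#' @param genetic_map Genetic map tibble (`marker_id`, `map_chrom`,
#'   `position_cM`).
#' @return Tibble: `marker_id`, `map_chrom`, `cM`, `phys_chrom`, `bp`,
#'   sorted by (map_chrom, cM).
#' @export
build_dotpoints <- function(loci, genetic_map) {
  loci |>
    inner_join(genetic_map, by = "marker_id", relationship = "many-to-many") |>
    select("marker_id", "map_chrom", cM = "position_cM",
           phys_chrom = "chrom", bp = "start") |>
    arrange(.data$map_chrom, .data$cM, .data$bp)
}

#' Detect inversions as descending runs in a dotplot
#'
#' Within each (map chromosome, physical chromosome) pair, points sorted by
#' cM are scanned for maximal runs of at least `min_markers` consecutive
#' points whose bp positions strictly decrease while cM increases
#' (negative-slope blocks). Runs whose physical span exceeds `min_span_mb`
#' are reported as inversions, with the run's first and last markers as
#' flanks. By default a single interior point violating monotonicity splits
#' the run; `skip_one = TRUE` tolerates one isolated violator (for noisy
#' real maps).
#'
#' @param points Dotplot tibble from [build_dotpoints()].
#' @param min_span_mb Minimum physical span (Mb) to report (default 1).
#' @param min_markers Minimum markers per run (default 3).
#' @param skip_one Tolerate a single interior violator (default FALSE).
#' @return Rearrangement call tibble: `kind`, `map_chrom`, `phys_chrom`,
#'   `start_marker`, `end_marker`, `cM_lo`, `cM_hi`, `bp_start`, `bp_end`,
#'   `n_markers`.
#' @export
detect_inversions <- function(points, min_span_mb = 1, min_markers = 3,
                              skip_one = FALSE) {
  empty <- rearrangement_call_tibble()
  runs <- points |>
    group_by(.data$map_chrom, .data$phys_chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      g <- g |> arrange(.data$cM, .data$bp)
      bp <- g$bp
      if (skip_one) bp <- drop_single_violators(bp)
      runs <- descending_runs(bp)
      purrr::map_dfr(runs, function(r) {
        idx <- r[1]:r[2]
        span <- abs(g$bp[r[1]] - g$bp[r[2]])
        if (length(idx) < min_markers || span <= min_span_mb * 1e6) return(NULL)
        tibble(
          kind = "inversion", map_chrom = g$map_chrom[1],
          phys_chrom = g$phys_chrom[1],
          start_marker = g$marker_id[r[1]], end_marker = g$marker_id[r[2]],
          cM_lo = g$cM[r[1]], cM_hi = g$cM[r[2]],
          bp_start = g$bp[r[1]], bp_end = g$bp[r[2]],
          n_markers = length(idx)
        )
      })
    })
  if (nrow(runs) == 0) empty else runs
}

rearrangement_call_tibble <- function() {
  tibble(kind = character(), map_chrom = character(), phys_chrom = character(),
         start_marker = character(), end_marker = character(),
         cM_lo = numeric(), cM_hi = numeric(),
         bp_start = numeric(), bp_end = numeric(), n_markers = integer())
}

# maximal runs of strictly decreasing values; returns list of c(first, last)
descending_runs <- function(bp) {
  n <- length(bp)
  if (n < 2) return(list())
  dec <- diff(bp) < 0
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) out[[length(out) + 1]] <- c(starts[k], ends[k] + 1L)
  }
  out
}

# replace single interior ascents flanked by descents with NA-skip:
# returns bp with lone violators interpolated so the run continues
drop_single_violators <- function(bp) {
  n <- length(bp)
  if (n < 3) return(bp)
  for (i in 2:(n - 1)) {
    if (bp[i] >= bp[i - 1] && bp[i + 1] < bp[i - 1] &&
        (i == 2 || bp[i - 1] < bp[i - 2])) {
      bp[i] <- (bp[i - 1] + bp[i + 1]) / 2
    }
  }
  bp
}

#' Detect translocations from dotplot chromosome assignments
#'
#' For each map chromosome, the majority physical chromosome of its points
#' is its home; any run of at least `min_markers` consecutive points (by
#' cM) lying on a single non-home physical chromosome is called a
#' translocation, reported with the bp interval the run occupies on the
#' foreign chromosome. A reciprocal translocation appears as two calls
#' with swapped (map, physical) chromosome pairs.
#'
#' @param points Dotplot tibble.
#' @param min_markers Minimum run length (default 3).
#' @return Rearrangement call tibble (see [detect_inversions()]).
#' @export
detect_translocations <- function(points, min_markers = 3) {
  calls <- points |>
    group_by(.data$map_chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      g <- g |> arrange(.data$cM, .data$bp)
      home <- names(sort(table(g$phys_chrom), decreasing = TRUE))[1]
      r <- rle(g$phys_chrom)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      purrr::map_dfr(seq_along(r$values), function(k) {
        if (r$values[k] == home || r$lengths[k] < min_markers) return(NULL)
        idx <- starts[k]:ends[k]
        tibble(
          kind = "translocation", map_chrom = g$map_chrom[1],
          phys_chrom = r$values[k],
          start_marker = g$marker_id[starts[k]], end_marker = g$marker_id[ends[k]],
          cM_lo = g$cM[starts[k]], cM_hi = g$cM[ends[k]],
          bp_start = min(g$bp[idx]), bp_end = max(g$bp[idx]),
          n_markers = length(idx)
        )
      })
    })
  if (nrow(calls) == 0) rearrangement_call_tibble() else calls
}

#' Complete rearrangement calls with spans and percentages
#'
#' Adds the reporting columns of a genome-variation table: genetic span and
#' its share of the source map, physical span in Mb and its share of the
#' chromosome. Spans use the outermost coordinates of the run's endpoint
#' markers; Mb spans and percentages are reported to two decimals.
#'
#' @param calls Rearrangement call tibble.
#' @param chrom_length_mb Named vector: physical chromosome length (Mb) per
#'   `phys_chrom`, or a single value recycled.
#' @param map_total_cm Named vector: total map length (cM) per `map_chrom`,
#'   or a single value recycled.
#' @return The calls with added `cM_span`, `map_total_cM`, `pct_of_map`,
#'   `Mb_span`, `chrom_length_Mb`, `pct_of_chrom`.
#' @export
summarize_rearrangement <- function(calls, chrom_length_mb, map_total_cm) {
  get <- function(v, key) if (is.null(names(v))) rep(v[1], length(key)) else unname(v[key])
  len <- get(chrom_length_mb, calls$phys_chrom)
  tot <- get(map_total_cm, calls$map_chrom)
  span_bp <- abs(calls$bp_end - calls$bp_start)
  cm_span <- abs(calls$cM_hi - calls$cM_lo)
  calls |>
    mutate(
      cM_span = cm_span, map_total_cM = tot,
      pct_of_map = round2(cm_span / tot * 100),
      Mb_span = round2(span_bp / 1e6),
      chrom_length_Mb = len,
      pct_of_chrom = round2(span_bp / 1e6 / len * 100)
    )
}
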