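#' Detect colinear anchor markers on one or more chromosomes
#'
#' Given loci that carry a genetic-map position, finds for each chromosome
#' the maximal-cardinality subset whose cM rank order equals the bp rank
#' order: the longest non-decreasing subsequence of cM values over loci
#' sorted by bp (cM ties are allowed and kept). Tie-breaking is
#' deterministic: among equally long colinear subsets the one reachable
#' through smaller bp positions is chosen. These loci anchor the genetic
#' map onto the assembly; all other loci receive interpolated positions.
#'
#' @param loci_map Tibble of map-bearing loci: `chrom`, `start`, `marker_id`,
#'   `map_cM` (and optionally `map_chrom`).
#' @return Anchor set tibble: `chrom`, `bp` (locus start), `cM`,
#'   `marker_id`, `map_chrom`, strictly increasing in bp and non-decreasing
#'   in cM within each chromosome. Chromosomes with fewer than two
#'   map-bearing loci are skipped with a warning.
#' @export
detect_colinear_anchors <- function(loci_map) {
  if (!"map_chrom" %in% names(loci_map)) loci_map$map_chrom <- loci_map$chrom
  out <- loci_map |>
    group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      if (nrow(g) < 2) {
        warn(sprintf("chromosome %s has %d map-bearing locus(i); skipped.",
                     g$chrom[1], nrow(g)))
        return(NULL)
      }
      g <- g |> arrange(.data$start, .data$map_cM, .data$marker_id)
      # drop duplicate bp so anchor bp are strictly increasing
      g <- g[!duplicated(g$start), ]
      idx <- lis_nondecreasing(g$map_cM)
      tibble(chrom = g$chrom[idx], bp = g$start[idx], cM = g$map_cM[idx],
             marker_id = g$marker_id[idx], map_chrom = g$map_chrom[idx])
    })
  bind_rows(out)
}

# Longest non-decreasing subsequence, O(n^2) DP with deterministic
# leftmost tie-breaking; returns the selected indices in order.
lis_nondecreasing <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  len <- rep(1L, n); pred <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        pred[i] <- j
      }
    }
  }
  # leftmost endpoint among maxima; predecessors were chosen leftmost-first
  i <- which.max(len)
  path <- integer(len[i])
  k <- len[i]
  while (i > 0L) { path[k] <- i; k <- k - 1L; i <- pred[i] }
  path
}

#' Assign cM positions to all loci by anchor interpolation
#'
#' A locus at physical position p between flanking anchors (b1, c1) and
#' (b2, c2) receives the linearly interpolated position
#' c1 + (p - b1) / (b2 - b1) * (c2 - c1). Loci outside the outermost
#' anchors are clamped to the nearest terminal anchor's cM and flagged
#' `extrapolated` (this prevents negative or runaway positions at
#' chromosome ends). Anchor loci keep their original map position with
#' flag `anchor`. Sorting a chromosome by bp yields non-decreasing cM.
#'
#' @param loci Locus tibble (`chrom`, `start`, `end`, `marker_id`, ...).
#' @param anchors Anchor set from [detect_colinear_anchors()].
#' @return The loci with added columns `cM`, `anchor`
#'   (anchor/interpolated/extrapolated) and `source_map_chrom`. Loci on
#'   chromosomes without anchors get `cM = NA` and flag `"unanchored"`.
#' @export
interpolate_cm <- function(loci, anchors) {
  interp_chr <- function(g) {
    a <- anchors[anchors$chrom == g$chrom[1], ]
    if (nrow(a) == 0) {
      return(g |> mutate(cM = NA_real_, anchor = "unanchored",
                         source_map_chrom = NA_character_))
    }
    a <- a |> arrange(.data$bp)
    p <- g$start
    i <- findInterval(p, a$bp)
    cM <- numeric(length(p)); flag <- character(length(p))
    below <- i == 0
    above <- i == nrow(a) & p > a$bp[nrow(a)]
    inside <- !below & !above
    cM[below] <- a$cM[1]; flag[below] <- "extrapolated"
    cM[above] <- a$cM[nrow(a)]; flag[above] <- "extrapolated"
    if (any(inside)) {
      ii <- i[inside]
      exact <- p[inside] == a$bp[ii]
      b1 <- a$bp[ii]; b2 <- a$bp[pmin(ii + 1L, nrow(a))]
      c1 <- a$cM[ii]; c2 <- a$cM[pmin(ii + 1L, nrow(a))]
      frac <- ifelse(b2 > b1, (p[inside] - b1) / (b2 - b1), 0)
      cM[inside] <- ifelse(exact, c1, c1 + frac * (c2 - c1))
      flag[inside] <- "interpolated"
    }
    is_anchor <- paste(g$marker_id, g$start) %in% paste(a$marker_id, a$bp)
    flag[is_anchor] <- "anchor"
    cM[is_anchor] <- a$cM[match(g$start[is_anchor], a$bp)]
    g |> mutate(cM = cM, anchor = flag, source_map_chrom = a$map_chrom[1])
  }
  loci |>
    group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(interp_chr) |>
    arrange(.data$chrom, .data$start)
}

#' Remove loci strikingly discrepant from the anchored frame
#'
#' Non-anchor loci that carry a map position are compared with the cM they
#' would receive by interpolation; loci whose map position differs by more
#' than `max_cm_offset` are dropped and reported. The default of 10 cM
#' targets gross disagreements (wrong arm, wrong assembly placement) while
#' leaving local ordering noise and modest rearrangements untouched.
#'
#' @param loci_map Map-bearing locus tibble (as for
#'   [detect_colinear_anchors()]).
#' @param anchors Anchor set.
#' @param max_cm_offset Maximum |map cM - interpolated cM| retained
#'   (default 10).
#' @return List with `kept` and `removed` tibbles; `removed` carries the
#'   `map_cM`, `interp_cM` and `offset` columns of the dropped loci.
#' @export
remove_discrepant <- function(loci_map, anchors, max_cm_offset = 10) {
  withcm <- interpolate_cm(loci_map, anchors)
  withcm$map_cM <- loci_map$map_cM[match(
    paste(withcm$marker_id, withcm$chrom, withcm$start),
    paste(loci_map$marker_id, loci_map$chrom, loci_map$start))]
  withcm <- withcm |>
    mutate(offset = abs(.data$map_cM - .data$cM))
  drop <- withcm$anchor != "anchor" & !is.na(withcm$offset) &
    withcm$offset > max_cm_offset
  list(
    kept = withcm[!drop, setdiff(names(withcm), c("cM", "anchor", "source_map_chrom", "offset"))],
    removed = withcm[drop, ] |> rename(interp_cM = "cM")
  )
}
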