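#' E-value thresholds for alignment filtering
#'
#' Marker-sequence alignments (RFLP probes and full SSR sequences) are kept
#' at E-value \eqn{\le} `evalue_sequence`; short SSR primer alignments,
#' which cannot reach low E-values, are kept at the much looser
#' `evalue_primer` bound. Both bounds are inclusive.
#'
#' @param evalue_sequence Threshold for RFLP/SSR sequence hits (default 1e-10).
#' @param evalue_primer Threshold for SSR primer hits (default 50).
#' @return A named list.
#' @export
filter_thresholds <- function(evalue_sequence = 1e-10, evalue_primer = 50) {
  if (evalue_sequence <= 0 || evalue_primer <= 0) {
    abort("E-value thresholds must be > 0.")
  }
  list(evalue_sequence = evalue_sequence, evalue_primer = evalue_primer)
}

#' Locate exact marker occurrences in a genome
#'
#' Reports every exact occurrence of each query sequence on both strands of
#' the genome, with E-value 0. Matching uses Aho-Corasick multi-pattern
#' search (via [Biostrings::matchPDict()]) when queries share one width,
#' and per-query search otherwise; the result is equivalent to an
#' exhaustive substring scan. A palindromic query (equal to its own reverse
#' complement) matches both strands over the same interval; such
#' double-reports are collapsed to a single plus-strand hit so copy numbers
#' are not inflated.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param queries Named character vector or `DNAStringSet` of query
#'   sequences (names are marker ids).
#' @param marker_class Class label stamped on the hits (`"RFLP"`,
#'   `"SSR_FWD"` or `"SSR_REV"`).
#' @param min_len Minimum query length (default 15); shorter queries error.
#' @param max_ambig Maximum number of non-ACGT letters tolerated per query;
#'   queries beyond the quota are skipped with a warning.
#' @return Hit tibble: `marker_id`, `marker_class`, `chrom`, `start`,
#'   `end`, `strand`, `evalue`, `percent_identity`, `align_len`
#'   (coordinates 1-based closed).
#' @export
locate_exact <- function(genome, queries, marker_class = "RFLP",
                         min_len = 15, max_ambig = 0) {
  q <- setNames(as.character(queries), names(queries))
  if (is.null(names(q)) || any(names(q) == "")) abort("queries must be named.")
  if (any(nchar(q) < min_len)) {
    abort(sprintf("all queries must be >= %d bp.", min_len))
  }
  n_ambig <- nchar(gsub("[ACGT]", "", toupper(q)))
  if (any(n_ambig > max_ambig)) {
    skip <- names(q)[n_ambig > max_ambig]
    warn(sprintf("skipping %d query(ies) with ambiguous letters: %s",
                 length(skip), paste(utils::head(skip, 3), collapse = ", ")))
    q <- q[n_ambig <= max_ambig]
  }
  empty <- tibble(marker_id = character(), marker_class = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), evalue = numeric(),
                  percent_identity = numeric(), align_len = integer())
  if (length(q) == 0) return(empty)

  pats <- Biostrings::DNAStringSet(toupper(q))
  names(pats) <- names(q)
  rc <- Biostrings::reverseComplement(pats)

  scan_one_strand <- function(pats, strand) {
    same_width <- length(unique(Biostrings::width(pats))) == 1
    purrr::map_dfr(names(genome), function(chr) {
      subject <- genome[[chr]]
      if (same_width) {
        m <- Biostrings::matchPDict(Biostrings::PDict(pats), subject)
        nn <- S4Vectors::elementNROWS(m)
        if (sum(nn) == 0) return(NULL)
        ir <- unlist(m, use.names = FALSE)
        tibble(marker_id = rep(names(pats), nn), chrom = chr,
               start = IRanges::start(ir), end = IRanges::end(ir),
               strand = strand)
      } else {
        purrr::map_dfr(names(pats), function(id) {
          m <- Biostrings::matchPattern(pats[[id]], subject)
          if (length(m) == 0) return(NULL)
          tibble(marker_id = id, chrom = chr, start = IRanges::start(m),
                 end = IRanges::end(m), strand = strand)
        })
      }
    })
  }

  hits <- bind_rows(scan_one_strand(pats, "+"), scan_one_strand(rc, "-"))
  if (nrow(hits) == 0) return(empty)
  hits |>
    mutate(marker_class = marker_class, evalue = 0,
           percent_identity = 100, align_len = .data$end - .data$start + 1L) |>
    arrange(.data$marker_id, .data$chrom, .data$start,
            factor(.data$strand, levels = c("+", "-"))) |>
    # palindromic rule: one hit per (marker, interval); '+' sorts first
    distinct(.data$marker_id, .data$chrom, .data$start, .data$end,
             .keep_all = TRUE) |>
    select("marker_id", "marker_class", "chrom", "start", "end", "strand",
           "evalue", "percent_identity", "align_len")
}

#' Locate all RFLP probes and SSR primers of a marker panel
#'
#' Convenience wrapper running [locate_exact()] for the RFLP probe set and
#' for both primers of every SSR marker, returning one combined hit table.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param rflp Named character vector / `DNAStringSet` of RFLP probes
#'   (or `NULL`).
#' @param ssr_primers Tibble with `marker_id`, `fwd_seq`, `rev_seq`
#'   (or `NULL`).
#' @return Combined hit tibble (see [locate_exact()]), with `marker_class`
#'   of `RFLP`, `SSR_FWD` or `SSR_REV`.
#' @export
locate_markers <- function(genome, rflp = NULL, ssr_primers = NULL) {
  out <- list()
  if (!is.null(rflp) && length(rflp) > 0) {
    out$rflp <- locate_exact(genome, rflp, "RFLP")
  }
  if (!is.null(ssr_primers) && nrow(ssr_primers) > 0) {
    fwd <- setNames(ssr_primers$fwd_seq, ssr_primers$marker_id)
    rev <- setNames(ssr_primers$rev_seq, ssr_primers$marker_id)
    out$fwd <- locate_exact(genome, fwd, "SSR_FWD")
    out$rev <- locate_exact(genome, rev, "SSR_REV")
  }
  bind_rows(out)
}

#' Filter alignment hits by class-specific E-value thresholds
#'
#' Sequence hits (class `RFLP`) are kept iff their E-value is at or below
#' the sequence threshold; primer hits (classes `SSR_FWD`, `SSR_REV`) iff
#' at or below the primer threshold. Both comparisons are inclusive and row
#' order is preserved. The operation is idempotent.
#'
#' @param hits Hit tibble with `marker_class` and `evalue` columns.
#' @param thresholds A [filter_thresholds()] list.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  cutoff <- ifelse(hits$marker_class %in% c("SSR_FWD", "SSR_REV"),
                   thresholds$evalue_primer, thresholds$evalue_sequence)
  hits[hits$evalue <= cutoff, ]
}
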