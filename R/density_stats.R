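#' Sliding-window marker density
#'
#' Counts marker loci in sliding windows of `window_bp` at `step_bp` steps
#' from position 0 to the end of each chromosome. Windows are 0-based
#' half-open `[k*step, k*step + window)` with the terminal window truncated
#' at the chromosome end; a locus is counted in a window iff its start
#' coordinate lies inside, so one locus contributes to every overlapping
#' step-window.
#'
#' @param loci Locus tibble with `chrom` and `start` (1-based).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_bp Window size (default 1 Mb).
#' @param step_bp Step size (default 100 kb).
#' @return Tibble: `chrom`, `window_start` (0-based), `window_end`
#'   (exclusive, truncated), `n_loci`.
#' @export
window_density <- function(loci, chrom_lengths, window_bp = 1e6, step_bp = 1e5) {
  missing <- setdiff(unique(loci$chrom), names(chrom_lengths))
  if (length(missing)) {
    abort(sprintf("chromosome(s) absent from chrom_lengths: %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    w <- seq(0, L - 1, by = step_bp)
    starts <- sort(loci$start[loci$chrom == chr])
    # count of loci with w < start <= w + window
    n <- findInterval(pmin(w + window_bp, L), starts) - findInterval(w, starts)
    tibble(chrom = chr, window_start = w, window_end = pmin(w + window_bp, L),
           n_loci = as.integer(n))
  })
}

#' Marker map density and coverage summary
#'
#' Per-chromosome locus counts and kb-per-locus, plus genome-level
#' statistics: mean kb per locus (total genome length over total loci),
#' loci per annotated gene (one decimal), the least-populated sliding
#' window, assembly coverage percent (two decimals), and the Pearson
#' correlation between per-chromosome locus counts and chromosome lengths.
#'
#' @param loci Locus tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_genes Number of annotated genes.
#' @param assembled_bp Anchored/assembled genome length (bp).
#' @param total_bp Total genome length (bp); also the kb-per-locus
#'   denominator.
#' @param window_bp,step_bp Passed to [window_density()].
#' @return A list of class `wgmm_density_summary` with `per_chromosome`
#'   and `genome` tibbles and the `windows` table.
#' @export
density_summary <- function(loci, chrom_lengths, n_genes, assembled_bp,
                            total_bp, window_bp = 1e6, step_bp = 1e5) {
  n_total <- nrow(loci)
  if (n_total == 0) abort("no loci: density statistics are undefined.")
  per_chr <- tibble(chrom = names(chrom_lengths),
                    length_bp = unname(chrom_lengths)) |>
    left_join(count(loci, .data$chrom, name = "n_loci"), by = "chrom") |>
    mutate(n_loci = dplyr::coalesce(.data$n_loci, 0L),
           kb_per_locus = ifelse(.data$n_loci > 0,
                                 round(.data$length_bp / 1000 / .data$n_loci, 1),
                                 NA_real_))
  win <- window_density(loci, chrom_lengths, window_bp, step_bp)
  corr <- if (nrow(per_chr) >= 3 && stats::sd(per_chr$n_loci) > 0 &&
              stats::sd(per_chr$length_bp) > 0) {
    chrom_size_correlation(per_chr$n_loci, per_chr$length_bp)
  } else {
    list(r = NA_real_, p = NA_real_)
  }
  genome <- tibble(
    n_loci = n_total,
    mean_kb_per_locus = round(total_bp / 1000 / n_total, 1),
    loci_per_gene = round(n_total / n_genes, 1),
    min_window_count = min(win$n_loci),
    coverage_pct = round2(assembled_bp / total_bp * 100),
    pearson_r = corr$r, pearson_p = corr$p
  )
  structure(list(per_chromosome = per_chr, genome = genome, windows = win),
            class = "wgmm_density_summary")
}

#' @export
print.wgmm_density_summary <- function(x, ...) {
  cat("Marker density summary\n")
  print(x$per_chromosome)
  print(x$genome)
  invisible(x)
}

#' @export
tidy.wgmm_density_summary <- function(x, ...) x$per_chromosome

#' @export
glance.wgmm_density_summary <- function(x, ...) x$genome

#' Correlation of per-chromosome locus counts with chromosome size
#'
#' Sample Pearson correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param n_loci Per-chromosome locus counts.
#' @param lengths Chromosome lengths (same order).
#' @return List with `r` and `p`.
#' @export
chrom_size_correlation <- function(n_loci, lengths) {
  if (length(n_loci) != length(lengths) || length(n_loci) < 3) {
    abort("need >= 3 paired observations.")
  }
  if (stats::sd(n_loci) == 0 || stats::sd(lengths) == 0) {
    abort("zero variance: correlation undefined.")
  }
  ct <- cor.test(n_loci, lengths, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
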