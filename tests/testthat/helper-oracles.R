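# Independent brute-force oracles. These deliberately use plain loops and
# base R so they share no code path with the package implementation.

# every exact occurrence of `query` on both strands of a character genome;
# palindromic double-reports collapsed to one interval
oracle_substring_scan <- function(genome_chr, query) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  out <- list()
  for (chr in names(genome_chr)) {
    subj <- genome_chr[[chr]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else rc
      pos <- c()
      from <- 1L
      repeat {
        hit <- regexpr(pat, substr(subj, from, nchar(subj)), fixed = TRUE)
        if (hit == -1) break
        pos <- c(pos, from + hit - 1L)
        from <- from + hit
      }
      if (length(pos)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = pos, end = pos + nchar(pat) - 1L, strand = strand
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), ]
  res[!duplicated(res[, c("chrom", "start", "end")]), ]
}

# single-linkage clustering of intervals by pairwise inner gap <= dist,
# via explicit transitive closure of the all-pairs adjacency matrix
oracle_single_linkage <- function(starts, ends, dist) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
    adj[i, j] <- gap <= dist
  }
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[adj[i, ]] <- k
    }
  }
  spans <- lapply(split(seq_len(n), comp), function(idx) {
    c(start = min(starts[idx]), end = max(ends[idx]))
  })
  spans <- do.call(rbind, spans)
  spans[order(spans[, "start"]), , drop = FALSE]
}

# nearest-first pairing, written as transparent repeated global scans:
# all convergent (plus upstream of minus, distinct primer roles) pairs are
# enumerated, the smallest-distance pair accepted, its hits removed, repeat
oracle_pair_scan <- function(hits, max_dist) {
  hits$used <- FALSE
  loci <- list()
  repeat {
    best <- NULL
    for (i in seq_len(nrow(hits))) for (j in seq_len(nrow(hits))) {
      if (i == j || hits$used[i] || hits$used[j]) next
      if (hits$strand[i] != "+" || hits$strand[j] != "-") next
      if (hits$marker_class[i] == hits$marker_class[j]) next
      d <- hits$start[j] - hits$end[i]
      if (d < 1 || d > max_dist) next
      key <- c(d, hits$start[i], hits$start[j])
      if (is.null(best) ||
          key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2]) ||
          (key[1] == best$key[1] && key[2] == best$key[2] && key[3] < best$key[3])) {
        best <- list(i = i, j = j, key = key)
      }
    }
    if (is.null(best)) break
    hits$used[c(best$i, best$j)] <- TRUE
    loci[[length(loci) + 1]] <- c(start = hits$start[best$i], end = hits$end[best$j])
  }
  if (!length(loci)) return(data.frame(start = numeric(), end = numeric()))
  res <- as.data.frame(do.call(rbind, loci))
  res[order(res$start), , drop = FALSE]
}

# maximum-cardinality colinear subset by exhaustive subset enumeration
# (x sorted by bp); returns the best size and one witness subset chosen
# with the same leftmost preference the package documents
oracle_max_colinear <- function(x) {
  n <- length(x)
  best <- integer()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= length(best)) next
    if (all(diff(x[idx]) >= 0)) best <- idx
  }
  best
}

# maximal strictly-descending runs by checking every (i, j) window
oracle_descending_runs <- function(bp) {
  n <- length(bp)
  runs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    win <- bp[i:j]
    if (any(diff(win) >= 0)) next
    left_ext <- i > 1 && bp[i - 1] > bp[i]
    right_ext <- j < n && bp[j + 1] < bp[j]
    if (!left_ext && !right_ext) runs[[length(runs) + 1]] <- c(i, j)
  }
  runs
}

# all-pairs domain-overlap adjudication, plain loops
oracle_overlap_filter <- function(hits, cutoff) {
  keep <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (hits$evalue[i] > cutoff) next
    ok <- TRUE
    for (j in seq_len(nrow(hits))) {
      if (j == i) next
      if (hits$protein_id[j] != hits$protein_id[i]) next
      if (hits$accession[j] == hits$accession[i]) next
      overlap <- hits$env_start[j] <= hits$env_end[i] &&
        hits$env_start[i] <= hits$env_end[j]
      if (overlap && hits$evalue[j] < hits$evalue[i]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, ]
}

# connected components of the interval-overlap graph by BFS
oracle_overlap_components <- function(starts, ends) {
  n <- length(starts)
  comp <- rep(NA_integer_, n); k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[i])) next
      comp[i] <- k
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && starts[j] <= ends[i] && starts[i] <= ends[j]) {
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# textbook Pearson r and two-sided p from the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

random_hit_tibble <- function(n, chrom = "c1", max_pos = 1e5, width = 50) {
  s <- sample.int(max_pos, n)
  tibble::tibble(marker_id = "m1", marker_class = "RFLP", chrom = chrom,
                 start = s, end = s + width - 1L, evalue = 0)
}
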