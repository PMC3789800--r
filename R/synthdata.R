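#' Configuration for the synthetic marker-map study
#'
#' Builds the parameter set for [simulate_bundle()]. The defaults describe a
#' compact but fully featured study: a four-chromosome genome carrying two
#' thousand sequence-tagged markers whose copy-number distribution follows
#' the empirical single-to-five-copy frequencies observed for cotton
#' RFLP/SSR marker sets, a genetic map colinear with the assembly except for
#' two planted multi-megabase inversions and one reciprocal translocation,
#' RGA (resistance gene analog) genes arranged in clusters, and QTL peaks
#' forming multi-trait hotspots.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of every chromosome (bp).
#' @param n_rflp,n_ssr Number of RFLP and SSR markers (decoys included).
#' @param copy_number_weights Probability weights for 1..`length(weights)`
#'   genomic copies per planted marker. Must sum to 1.
#' @param marker_len_bp Length of RFLP probe sequences (bp).
#' @param primer_len_bp SSR primer length (bp).
#' @param amplicon_bp SSR amplicon length, outer primer end to outer primer
#'   end (bp). Must stay below the primer pairing distance (1 kb) so planted
#'   pairs are recoverable.
#' @param decoy_frac Fraction of markers planted nowhere (exercises the
#'   unmapped path).
#' @param cm_per_mb Genetic map scale (cM per Mb).
#' @param map_fraction Fraction of single-copy markers put on the genetic map.
#' @param inversions Data frame with columns `chrom` (chromosome index),
#'   `start`, `end` (bp): intervals whose marker order is reversed on the map.
#' @param translocations Data frame with columns `donor`, `acceptor`
#'   (chromosome indices), `start`, `end` (bp): markers physically on the
#'   donor interval are assigned to the acceptor map chromosome.
#' @param n_genes Number of annotated genes.
#' @param rga_cluster_sizes Integer vector: sizes of planted RGA clusters.
#' @param n_rga_singletons Isolated RGA genes (must not become clusters).
#' @param n_decoy_nbs Genes with an NBS hit dominated by an overlapping
#'   stronger domain (must be rejected downstream).
#' @param n_qtl Total number of QTL.
#' @param hotspot_spec Data frame with columns `chrom`, `center_bp`,
#'   `n_traits`: planted multi-trait QTL hotspots.
#' @param hotspot_window_cm Width of the cM window holding a hotspot's peaks.
#' @param seed Integer RNG seed; every stage derives its stream from it.
#' @return A list of class `wgmm_synth_config`.
#' @export
synth_config <- function(n_chromosomes = 4,
                         chrom_length_bp = 12e6,
                         n_rflp = 1000,
                         n_ssr = 1000,
                         copy_number_weights = c(0.3491, 0.2157, 0.1297, 0.0643, 0.2412),
                         marker_len_bp = 60,
                         primer_len_bp = 20,
                         amplicon_bp = 400,
                         decoy_frac = 0.05,
                         cm_per_mb = 3,
                         map_fraction = 0.5,
                         inversions = data.frame(
                           chrom = c(1L, 2L),
                           start = c(4e6, 5e6),
                           end   = c(7e6, 7.5e6)
                         ),
                         translocations = data.frame(
                           donor    = c(3L, 4L),
                           acceptor = c(4L, 3L),
                           start    = c(8e6, 8e6),
                           end      = c(10e6, 10e6)
                         ),
                         n_genes = 2000,
                         rga_cluster_sizes = c(3L, 7L, 2L, 4L),
                         n_rga_singletons = 3,
                         n_decoy_nbs = 5,
                         n_qtl = 30,
                         hotspot_spec = data.frame(
                           chrom     = c(1L, 2L, 4L),
                           center_bp = c(9e6, 2e6, 3e6),
                           n_traits  = c(4L, 3L, 5L)
                         ),
                         hotspot_window_cm = 0.05,
                         seed = 42L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_rflp = as.integer(n_rflp), n_ssr = as.integer(n_ssr),
    copy_number_weights = as.numeric(copy_number_weights),
    marker_len_bp = as.integer(marker_len_bp),
    primer_len_bp = as.integer(primer_len_bp),
    amplicon_bp = as.integer(amplicon_bp),
    decoy_frac = decoy_frac,
    cm_per_mb = cm_per_mb,
    map_fraction = map_fraction,
    inversions = as_tibble(inversions),
    translocations = as_tibble(translocations),
    n_genes = as.integer(n_genes),
    rga_cluster_sizes = as.integer(rga_cluster_sizes),
    n_rga_singletons = as.integer(n_rga_singletons),
    n_decoy_nbs = as.integer(n_decoy_nbs),
    n_qtl = as.integer(n_qtl),
    hotspot_spec = as_tibble(hotspot_spec),
    hotspot_window_cm = hotspot_window_cm,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "wgmm_synth_config")
}

#' Empty rearrangement / hotspot specifications
#'
#' Convenience constructors for configurations without planted structural
#' variation or QTL hotspots.
#' @return `no_rearrangements()`: a list with zero-row `inversions` and
#'   `translocations` data frames. `no_hotspots()`: a zero-row hotspot
#'   specification.
#' @export
no_rearrangements <- function() {
  list(
    inversions = data.frame(chrom = integer(), start = numeric(), end = numeric()),
    translocations = data.frame(donor = integer(), acceptor = integer(),
                                start = numeric(), end = numeric())
  )
}

#' @rdname no_rearrangements
#' @export
no_hotspots <- function() {
  data.frame(chrom = integer(), center_bp = numeric(), n_traits = integer())
}

validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$copy_number_weights) - 1) > 1e-9) {
    abort("`copy_number_weights` must sum to 1 (within 1e-9).")
  }
  if (cfg$chrom_length_bp < 10 * cfg$marker_len_bp) {
    abort("chromosomes must be at least 10 x `marker_len_bp` long.")
  }
  if (cfg$amplicon_bp < 2 * cfg$primer_len_bp + 10) {
    abort("`amplicon_bp` must leave room for both primers.")
  }
  check_iv <- function(df, chrom_col, label) {
    if (nrow(df) == 0) return(invisible())
    bad <- df$start < 1 | df$end > cfg$chrom_length_bp | df$start >= df$end |
      df[[chrom_col]] < 1 | df[[chrom_col]] > cfg$n_chromosomes
    if (any(bad)) abort(paste0("planted ", label, " intervals must lie within their chromosome."))
  }
  check_iv(cfg$inversions, "chrom", "inversion")
  check_iv(cfg$translocations, "donor", "translocation")
  inv <- cfg$inversions
  if (nrow(inv) > 1) {
    for (i in seq_len(nrow(inv) - 1)) for (j in (i + 1):nrow(inv)) {
      if (inv$chrom[i] == inv$chrom[j] &&
          inv$start[i] <= inv$end[j] && inv$start[j] <= inv$end[i]) {
        abort("inversion intervals must be pairwise disjoint.")
      }
    }
  }
  invisible(cfg)
}

chrom_names <- function(cfg) sprintf("Chr%02d", seq_len(cfg$n_chromosomes))

#' Generate the synthetic genome and gene annotation
#'
#' Emits a random-sequence genome of the configured shape plus a
#' non-overlapping, physically ordered gene annotation, and the empty truth
#' table the later stages fill in. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]),
#'   `genes` (tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `order_rank`) and `truth` (skeleton list).
#' @export
generate_genome <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed + 1L, {
    L <- cfg$chrom_length_bp
    seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) random_dna(L), "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names(cfg)

    per_chr <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
    per_chr[seq_len(cfg$n_genes %% cfg$n_chromosomes)] <-
      per_chr[seq_len(cfg$n_genes %% cfg$n_chromosomes)] + 1L
    gene_len <- 3000
    genes <- purrr::map2_dfr(chrom_names(cfg), per_chr, function(chr, ng) {
      pitch <- floor((L - gene_len - 2000) / ng)
      start <- (seq_len(ng) - 1L) * pitch + 1L + sample.int(min(2000, pitch - gene_len), ng, replace = TRUE)
      tibble(
        gene_id = sprintf("%s.g%04d", chr, seq_len(ng)),
        chrom = chr, start = start, end = start + gene_len - 1L,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        order_rank = seq_len(ng)
      )
    })
  })
  list(genome = genome, genes = genes,
       truth = list(marker_copies = NULL, rearrangements = NULL,
                    rga_genes = NULL, rga_clusters = NULL, qtl_hotspots = NULL))
}

#' Plant marker sequences into the synthetic genome
#'
#' Each RFLP marker is copied verbatim into `k` genome locations (`k` drawn
#' from the copy-number weights), on either strand; each SSR marker is a
#' forward/reverse primer pair flanking an amplicon shorter than the pairing
#' distance. Same-chromosome copies of one marker are separated by more than
#' the downstream deduplication distance, so the truth copy number equals
#' the recoverable copy number by construction. A fraction of decoy markers
#' is planted nowhere.
#'
#' @param sim Result of [generate_genome()].
#' @param config The [synth_config()].
#' @return `sim` with the genome edited in place, plus `rflp` (a
#'   [Biostrings::DNAStringSet] of probe sequences), `ssr_primers` (tibble:
#'   `marker_id`, `fwd_seq`, `rev_seq`) and `truth$marker_copies` (tibble:
#'   `marker_id`, `marker_class`, `chrom`, `start`, `end`, `strand`).
#' @export
plant_markers <- function(sim, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 2L, {
    cap <- length(cfg$copy_number_weights)
    jitter_max <- 500L
    feature_max <- max(cfg$marker_len_bp, cfg$amplicon_bp)
    slot_bp <- 5000L + jitter_max + feature_max + 300L
    L <- cfg$chrom_length_bp

    rflp_ids <- sprintf("RFLP%04d", seq_len(cfg$n_rflp))
    ssr_ids  <- sprintf("SSR%04d",  seq_len(cfg$n_ssr))
    rflp_seq <- vapply(rflp_ids, function(i) random_dna(cfg$marker_len_bp), "")
    fwd_seq  <- vapply(ssr_ids, function(i) random_dna(cfg$primer_len_bp), "")
    rev_seq  <- vapply(ssr_ids, function(i) random_dna(cfg$primer_len_bp), "")

    markers <- tibble(
      marker_id = c(rflp_ids, ssr_ids),
      marker_class = rep(c("RFLP", "SSR"), c(cfg$n_rflp, cfg$n_ssr))
    )
    n_decoy <- round(cfg$decoy_frac * nrow(markers))
    markers$decoy <- FALSE
    markers$decoy[sample.int(nrow(markers), n_decoy)] <- TRUE
    markers$copies <- ifelse(
      markers$decoy, 0L,
      sample.int(cap, nrow(markers), replace = TRUE, prob = cfg$copy_number_weights)
    )

    slots <- tidyr::expand_grid(
      chrom = chrom_names(cfg),
      slot_start = seq(1, L - slot_bp, by = slot_bp)
    )
    total <- sum(markers$copies)
    if (total > nrow(slots)) {
      abort(sprintf("requested %d marker placements exceed genome capacity (%d slots).",
                    total, nrow(slots)))
    }
    slots <- slots[sample.int(nrow(slots), total), ]

    plan <- markers[rep(seq_len(nrow(markers)), markers$copies),
                    c("marker_id", "marker_class")]
    plan$chrom <- slots$chrom
    plan$start <- slots$slot_start + sample.int(jitter_max, total, replace = TRUE) - 1L
    plan$strand <- sample(c("+", "-"), total, replace = TRUE)
    plan$strand[plan$marker_class == "SSR"] <- "+"

    feat_len <- ifelse(plan$marker_class == "RFLP", cfg$marker_len_bp, cfg$amplicon_bp)
    plan$end <- plan$start + feat_len - 1L

    insert_len <- cfg$amplicon_bp - 2L * cfg$primer_len_bp
    seq_of <- function(i) {
      row <- plan[i, ]
      if (row$marker_class == "RFLP") {
        s <- rflp_seq[[row$marker_id]]
        if (row$strand == "-") revcomp_chr(s) else s
      } else {
        paste0(fwd_seq[[row$marker_id]], random_dna(insert_len),
               revcomp_chr(rev_seq[[row$marker_id]]))
      }
    }
    plan$planted_seq <- vapply(seq_len(nrow(plan)), seq_of, "")

    genome <- sim$genome
    for (chr in chrom_names(cfg)) {
      rows <- plan[plan$chrom == chr, ]
      if (nrow(rows) == 0) next
      genome[[chr]] <- Biostrings::replaceAt(
        genome[[chr]],
        IRanges::IRanges(start = rows$start, end = rows$end),
        Biostrings::DNAStringSet(rows$planted_seq)
      )
    }

    sim$genome <- genome
    sim$rflp <- Biostrings::DNAStringSet(rflp_seq)
    sim$ssr_primers <- tibble(marker_id = ssr_ids, fwd_seq = unname(fwd_seq),
                              rev_seq = unname(rev_seq))
    sim$markers <- markers
    sim$truth$marker_copies <- plan |>
      select("marker_id", "marker_class", "chrom", "start", "end", "strand") |>
      arrange(.data$marker_id, .data$chrom, .data$start)
  })
  sim
}

#' Generate a genetic map colinear with the genome except for planted
#' rearrangements
#'
#' A random subset of single-copy markers receives a cM position equal to
#' the map scale times its physical position. Inside each planted inversion
#' the cM coordinate is reflected, so cM order runs against physical order;
#' markers inside a planted translocation interval are reassigned to the
#' acceptor map chromosome (appended beyond its own map, preserving internal
#' order). Map rows are sorted by chromosome then cM.
#'
#' @inheritParams plant_markers
#' @return `sim` plus `genetic_map` (tibble: `marker_id`, `map_chrom`,
#'   `position_cM`) and `truth$rearrangements`.
#' @export
generate_genetic_map <- function(sim, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 3L, {
    copies <- sim$truth$marker_copies
    single <- copies |>
      group_by(.data$marker_id) |>
      filter(n() == 1) |>
      ungroup()
    keep <- sort(sample.int(nrow(single), round(cfg$map_fraction * nrow(single))))
    mp <- single[keep, ] |>
      mutate(map_chrom = .data$chrom,
             position_cM = cfg$cm_per_mb * .data$start / 1e6)

    cn <- chrom_names(cfg)
    max_base_cm <- cfg$cm_per_mb * cfg$chrom_length_bp / 1e6

    rearr <- list()
    inv <- cfg$inversions
    for (i in seq_len(nrow(inv))) {
      chr <- cn[inv$chrom[i]]
      sel <- mp$chrom == chr & mp$start >= inv$start[i] & mp$start <= inv$end[i]
      if (sum(sel) < 3) {
        warn(sprintf("inversion %d on %s contains %d mapped markers (< 3): undetectable.",
                     i, chr, sum(sel)))
      }
      mp$position_cM[sel] <- cfg$cm_per_mb * (inv$start[i] + inv$end[i] - mp$start[sel]) / 1e6
      ids <- mp$marker_id[sel][order(mp$start[sel])]
      rearr[[length(rearr) + 1]] <- tibble(
        kind = "inversion", map_chrom = chr, phys_chrom = chr,
        start_bp = inv$start[i], end_bp = inv$end[i],
        n_markers = sum(sel), marker_ids = list(ids)
      )
    }
    tr <- cfg$translocations
    for (i in seq_len(nrow(tr))) {
      donor <- cn[tr$donor[i]]; acceptor <- cn[tr$acceptor[i]]
      sel <- mp$chrom == donor & mp$start >= tr$start[i] & mp$start <= tr$end[i]
      mp$map_chrom[sel] <- acceptor
      mp$position_cM[sel] <- max_base_cm + 2 +
        cfg$cm_per_mb * (mp$start[sel] - tr$start[i]) / 1e6
      ids <- mp$marker_id[sel][order(mp$start[sel])]
      rearr[[length(rearr) + 1]] <- tibble(
        kind = "translocation", map_chrom = acceptor, phys_chrom = donor,
        start_bp = tr$start[i], end_bp = tr$end[i],
        n_markers = sum(sel), marker_ids = list(ids)
      )
    }

    sim$genetic_map <- mp |>
      select("marker_id", "map_chrom", position_cM = "position_cM") |>
      arrange(.data$map_chrom, .data$position_cM, .data$marker_id)
    sim$truth$rearrangements <- if (length(rearr)) bind_rows(rearr) else
      tibble(kind = character(), map_chrom = character(), phys_chrom = character(),
             start_bp = numeric(), end_bp = numeric(), n_markers = integer(),
             marker_ids = list())
    sim$truth$map_truth_cm <- single[keep, ] |>
      mutate(truth_cM = cfg$cm_per_mb * .data$start / 1e6) |>
      select("marker_id", "chrom", "start", "truth_cM")
  })
  sim
}

# Pfam accessions used by the generator: NB-ARC (NBS), TIR, two LRR-clan
# families, and a protein-kinase domain used for decoys/background.
PF_NBS <- "PF00931"; PF_TIR <- "PF01582"
PF_LRR1 <- "PF13855"; PF_LRR2 <- "PF00560"; PF_KIN <- "PF00069"

#' Generate protein domain hits and coiled-coil segments for RGA truth
#'
#' Designated truth RGA genes receive a validated NBS (NB-ARC) hit plus,
#' depending on class, a TIR domain or an N-terminal coiled-coil segment and
#' LRR hits. Planted clusters occupy consecutive gene-order ranks with no
#' intervening gene. Decoy genes receive an NBS hit fully overlapped by a
#' kinase domain with lower E-value, which the downstream filter must
#' reject.
#'
#' @inheritParams plant_markers
#' @return `sim` plus `domain_hits` (tibble: `protein_id`, `accession`,
#'   `env_start`, `env_end`, `evalue`), `coils` (tibble: `protein_id`,
#'   `start`, `end`), and truth entries `rga_genes` / `rga_clusters`.
#' @export
generate_domain_hits <- function(sim, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 4L, {
    genes <- sim$genes
    cn <- chrom_names(cfg)
    classes <- c("TIR-NBS-LRR", "CC-NBS-LRR", "NBS-LRR", "TIR-NBS", "CC-NBS", "NBS")

    # Round-robin allocator: hands out runs of consecutive gene ranks per
    # chromosome, always leaving >= 3 non-RGA genes between allocations so
    # planted clusters cannot merge with neighbouring RGAs.
    cursor <- setNames(rep(5L, cfg$n_chromosomes), cn)
    alloc <- function(chrom_idx, len) {
      chr <- cn[(chrom_idx - 1L) %% cfg$n_chromosomes + 1L]
      r0 <- cursor[[chr]]
      g <- genes[genes$chrom == chr, ]
      members <- g[g$order_rank >= r0 & g$order_rank < r0 + len, ]
      if (nrow(members) < len) {
        abort("too few genes per chromosome for the requested RGA layout.")
      }
      cursor[[chr]] <<- r0 + len + 3L
      members
    }

    rga <- list(); clusters <- list()
    for (j in seq_along(cfg$rga_cluster_sizes)) {
      sz <- cfg$rga_cluster_sizes[j]
      members <- alloc(j, sz)
      rga[[length(rga) + 1]] <- members |>
        mutate(rga_class = classes[(seq_len(sz) + j) %% length(classes) + 1L],
               cluster_id = sprintf("truth_cluster%02d", j))
      clusters[[j]] <- tibble(
        cluster_id = sprintf("truth_cluster%02d", j), chrom = members$chrom[1],
        size = sz, gene_ids = list(members$gene_id),
        start = min(members$start), end = max(members$end)
      )
    }
    for (i in seq_len(cfg$n_rga_singletons)) {
      g <- alloc(i, 1L)
      rga[[length(rga) + 1]] <- g |>
        mutate(rga_class = classes[i %% length(classes) + 1L], cluster_id = NA_character_)
    }
    rga <- bind_rows(rga)

    decoys <- purrr::map_dfr(seq_len(cfg$n_decoy_nbs), function(i) alloc(i + 1L, 1L))

    hit <- function(id, acc, s, e, ev) {
      tibble(protein_id = id, accession = acc, env_start = s, env_end = e, evalue = ev)
    }
    hits <- list(); coils <- list()
    for (i in seq_len(nrow(rga))) {
      id <- rga$gene_id[i]; cl <- rga$rga_class[i]
      hits[[length(hits) + 1]] <- hit(id, PF_NBS, 150L, 450L, 10^-runif(1, 20, 40))
      if (grepl("TIR", cl)) {
        hits[[length(hits) + 1]] <- hit(id, PF_TIR, 10L, 120L, 10^-runif(1, 12, 25))
      }
      if (grepl("^CC", cl)) {
        coils[[length(coils) + 1]] <- tibble(protein_id = id, start = 5L, end = 60L)
      }
      if (grepl("LRR$", cl)) {
        hits[[length(hits) + 1]] <- hit(id, PF_LRR1, 480L, 620L, 10^-runif(1, 6, 12))
        hits[[length(hits) + 1]] <- hit(id, PF_LRR2, 640L, 760L, 10^-runif(1, 4, 8))
      }
    }
    for (i in seq_len(nrow(decoys))) {
      id <- decoys$gene_id[i]
      hits[[length(hits) + 1]] <- hit(id, PF_NBS, 150L, 450L, 1e-18)
      hits[[length(hits) + 1]] <- hit(id, PF_KIN, 100L, 500L, 1e-40)
    }
    bg <- genes |>
      anti_join(rga, by = "gene_id") |>
      anti_join(decoys, by = "gene_id")
    bg <- bg[sample.int(nrow(bg), round(0.1 * nrow(bg))), ]
    hits[[length(hits) + 1]] <- hit(bg$gene_id, PF_KIN, 30L, 280L, 10^-runif(nrow(bg), 30, 60))

    sim$domain_hits <- bind_rows(hits) |> arrange(.data$protein_id, .data$env_start)
    sim$coils <- if (length(coils)) bind_rows(coils) else
      tibble(protein_id = character(), start = integer(), end = integer())
    sim$truth$rga_genes <- rga |>
      select("gene_id", "chrom", "order_rank", "rga_class", "cluster_id")
    sim$truth$rga_clusters <- bind_rows(clusters)
    sim$truth$rga_decoys <- decoys$gene_id
  })
  sim
}

#' Generate QTL with planted multi-trait hotspots
#'
#' Each hotspot specification yields `n_traits` QTL with distinct fiber
#' trait codes whose peak cM positions fall inside one narrow window;
#' remaining QTL are scattered uniformly over the map with a single random
#' trait each.
#'
#' @inheritParams plant_markers
#' @return `sim` plus `qtl` (tibble: `name`, `trait`, `map_chrom`,
#'   `peak_cM`) and `truth$qtl_hotspots`.
#' @export
generate_qtl <- function(sim, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 5L, {
    cn <- chrom_names(cfg)
    hs <- cfg$hotspot_spec
    w <- cfg$hotspot_window_cm
    out <- list(); truth <- list()
    for (i in seq_len(nrow(hs))) {
      chr <- cn[hs$chrom[i]]
      center_cm <- cfg$cm_per_mb * hs$center_bp[i] / 1e6
      traits <- sample(FIBER_TRAITS, hs$n_traits[i])
      peaks <- center_cm + runif(hs$n_traits[i], -w / 2, w / 2)
      qnames <- sprintf("%s%02d.%d", traits, hs$chrom[i], i)
      out[[i]] <- tibble(name = qnames, trait = traits, map_chrom = chr, peak_cM = peaks)
      truth[[i]] <- tibble(map_chrom = chr, center_bp = hs$center_bp[i],
                           center_cM = center_cm, n_traits = hs$n_traits[i],
                           qtl_names = list(qnames))
    }
    n_rest <- cfg$n_qtl - sum(hs$n_traits)
    if (n_rest < 0) abort("`n_qtl` is smaller than the QTL implied by `hotspot_spec`.")
    if (n_rest > 0) {
      max_cm <- cfg$cm_per_mb * cfg$chrom_length_bp / 1e6
      traits <- sample(FIBER_TRAITS, n_rest, replace = TRUE)
      out[[length(out) + 1]] <- tibble(
        name = sprintf("%sbg.%02d", traits, seq_len(n_rest)),
        trait = traits,
        map_chrom = sample(cn, n_rest, replace = TRUE),
        peak_cM = runif(n_rest, 0.5, max_cm - 0.5)
      )
    }
    empty_qtl <- tibble(name = character(), trait = character(),
                        map_chrom = character(), peak_cM = numeric())
    sim$qtl <- bind_rows(empty_qtl, out) |>
      arrange(.data$map_chrom, .data$peak_cM)
    sim$truth$qtl_hotspots <- bind_rows(
      tibble(map_chrom = character(), center_bp = numeric(),
             center_cM = numeric(), n_traits = integer(), qtl_names = list()),
      truth)
  })
  sim
}

#' Simulate a complete marker-map study with known ground truth
#'
#' Runs every generator stage in order: genome and gene annotation, marker
#' planting, genetic map with rearrangements, domain hits, and QTL. The
#' result bundles every pipeline input plus the truth table used by
#' recovery tests. Identical configurations give identical bundles.
#'
#' @param config A [synth_config()].
#' @return A list of class `wgmm_bundle` with elements `genome`, `genes`,
#'   `rflp`, `ssr_primers`, `markers`, `genetic_map`, `domain_hits`,
#'   `coils`, `qtl`, `truth`, and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- synth_config(n_chromosomes = 2, chrom_length_bp = 5e5,
#'                     n_rflp = 20, n_ssr = 20, n_genes = 40,
#'                     inversions = no_rearrangements()$inversions,
#'                     translocations = no_rearrangements()$translocations,
#'                     n_qtl = 0, hotspot_spec = no_hotspots(),
#'                     rga_cluster_sizes = c(2L), seed = 1)
#' bundle <- simulate_bundle(cfg)
#' }
simulate_bundle <- function(config = synth_config()) {
  sim <- generate_genome(config)
  sim <- plant_markers(sim, config)
  sim <- generate_genetic_map(sim, config)
  sim <- generate_domain_hits(sim, config)
  sim <- generate_qtl(sim, config)
  sim$config <- config
  structure(sim, class = "wgmm_bundle")
}
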