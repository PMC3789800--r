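# Shared synthetic bundles, built once per test run. The default bundle is
# the package's standard study condition (see synth_config()); the
# "colinear" bundle is the same condition without planted rearrangements,
# used for interpolation-accuracy checks.

.wgmm_test_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.wgmm_test_cache$default)) {
    .wgmm_test_cache$default <- simulate_bundle(synth_config(seed = 42L))
  }
  .wgmm_test_cache$default
}

default_report <- function() {
  if (is.null(.wgmm_test_cache$default_report)) {
    b <- default_bundle()
    .wgmm_test_cache$default_report <- run_wgmm(
      genome = b$genome, rflp = b$rflp, ssr_primers = b$ssr_primers,
      genetic_map = b$genetic_map, genes = b$genes,
      domain_hits = b$domain_hits, coils = b$coils, qtl = b$qtl
    )
  }
  .wgmm_test_cache$default_report
}

colinear_bundle <- function() {
  if (is.null(.wgmm_test_cache$colinear)) {
    cfg <- synth_config(
      inversions = no_rearrangements()$inversions,
      translocations = no_rearrangements()$translocations,
      seed = 42L
    )
    .wgmm_test_cache$colinear <- simulate_bundle(cfg)
  }
  .wgmm_test_cache$colinear
}

# a small, fast configuration for module-level tests (~1 s to simulate)
tiny_config <- function(seed = 11L, ...) {
  args <- list(
    n_chromosomes = 2L, chrom_length_bp = 2e6, n_rflp = 40L, n_ssr = 40L,
    n_genes = 80L, n_qtl = 8L,
    inversions = data.frame(chrom = 1L, start = 2e5, end = 1.8e6),
    translocations = no_rearrangements()$translocations,
    rga_cluster_sizes = c(3L, 2L), n_rga_singletons = 2L, n_decoy_nbs = 2L,
    hotspot_spec = data.frame(chrom = 2L, center_bp = 1e6, n_traits = 3L),
    map_fraction = 1, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}
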