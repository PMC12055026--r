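# Shared fixture builders (all generated in code; nothing stored on disk).

# Random symmetric MSN-like matrix: correlations of random feature tables,
# zero diagonal.
random_msn <- function(n_regions, seed) {
  set.seed(seed)
  compute_msn(zscore_features(matrix(rnorm(n_regions * 5), n_regions,
                                     dimnames = list(
                                       sprintf("region_%04d", 1:n_regions),
                                       c("thickness", "volume", "area",
                                         "gauss_curv", "mean_curv")))))
}

# Small two-site cohort with a supplied effect map.
small_cohort <- function(n_regions = 60, n_per_group = c(AD = 15, NC = 15),
                         effect_map = numeric(n_regions),
                         site_offsets = c(0, 0.3), seed = 42) {
  generate_cohort(cohort_spec(n_regions = n_regions,
                              n_per_group = n_per_group, n_sites = 2,
                              effect_map = effect_map,
                              site_offsets = site_offsets, seed = seed))
}

# Two-block affinity: high within-block, low between.
block_affinity <- function(n_half = 3, within = 0.9, between = 0.1) {
  n <- 2 * n_half
  a <- matrix(between, n, n)
  a[1:n_half, 1:n_half] <- within
  a[(n_half + 1):n, (n_half + 1):n] <- within
  diag(a) <- 1
  a
}
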