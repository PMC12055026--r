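#' Specify a synthetic cohort
#'
#' Bundles the design of a simulated case-control morphometry study: region
#' and group counts, a per-region signed effect map applied to the AD group's
#' feature means (in units of the unit noise SD), additive per-site feature
#' offsets, and covariate distributions. The defaults mirror a desk-scale
#' version of a two-site AD/NC cohort with five morphometric features per
#' region.
#'
#' @param n_regions number of cortical parcels (400 at desk scale; 1533
#'   mirrors the DK-1533 parcellation).
#' @param n_per_group length-2 named vector `c(AD = , NC = )` of subjects per
#'   group.
#' @param n_sites number of acquisition sites.
#' @param effect_map numeric vector of length `n_regions`: standardized mean
#'   shift added to every feature of AD subjects in that region. Zero allowed.
#' @param site_offsets `n_sites` x 5 matrix of additive feature shifts per
#'   site (recycled from a vector of length `n_sites`, applied to all
#'   features). Defaults to zeros.
#' @param site_scale optional `n_sites` vector of multiplicative noise-scale
#'   factors per site, exercising ComBat's scale component. Default all 1.
#' @param covariates list with elements `age = c(mean, sd)`,
#'   `education = c(mean, sd)`, `p_female` (probability sex == 1). Age is
#'   clipped to [55, 95], education to [6, 22].
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 400,
                        n_per_group = c(AD = 100, NC = 100),
                        n_sites = 2,
                        effect_map = numeric(n_regions),
                        site_offsets = NULL,
                        site_scale = rep(1, n_sites),
                        covariates = list(age = c(73, 6),
                                          education = c(16, 2.5),
                                          p_female = 0.5),
                        seed = 1L) {
  stop_if(!is_count(n_regions), "`n_regions` must be a positive integer")
  stop_if(length(n_per_group) != 2 || any(n_per_group < 1),
          "`n_per_group` must hold two positive counts")
  if (is.null(names(n_per_group))) names(n_per_group) <- c("AD", "NC")
  stop_if(!is_count(n_sites), "`n_sites` must be a positive integer")
  stop_if(length(effect_map) != n_regions,
          sprintf("`effect_map` must have one entry per region (%d), got %d",
                  n_regions, length(effect_map)))
  stop_if(anyNA(effect_map) || !is.numeric(effect_map),
          "`effect_map` must be numeric without NA")
  if (is.null(site_offsets)) {
    site_offsets <- matrix(0, n_sites, length(MSN_FEATURES))
  } else if (is.vector(site_offsets)) {
    stop_if(length(site_offsets) != n_sites,
            "`site_offsets` vector must have one entry per site")
    site_offsets <- matrix(site_offsets, n_sites, length(MSN_FEATURES))
  }
  stop_if(nrow(site_offsets) != n_sites,
          "`site_offsets` must have one row per site")
  stop_if(length(site_scale) != n_sites || any(site_scale <= 0),
          "`site_scale` must hold one positive factor per site")
  structure(list(n_regions = as.integer(n_regions),
                 n_features = 5L,
                 n_per_group = n_per_group,
                 n_sites = as.integer(n_sites),
                 effect_map = as.numeric(effect_map),
                 site_offsets = site_offsets,
                 site_scale = as.numeric(site_scale),
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Smooth regional mean profiles along the 1-D region ordering. Each feature is
# a different low-frequency mixture, so neighbouring regions have similar
# 5-feature profiles and the MSN acquires non-trivial block structure with a
# meaningful principal axis.
region_mean_profiles <- function(n_regions, n_features = 5L) {
  u <- seq(0, 1, length.out = n_regions)
  vapply(seq_len(n_features), function(f) {
    1.5 * sin(2 * pi * (u + f / n_features)) +
      1.0 * cos(2 * pi * 2 * (u - f / 7)) +
      0.5 * sin(2 * pi * 3 * u + f)
  }, numeric(n_regions))
}

#' Generate a synthetic morphometry cohort
#'
#' Draws one regions x 5 feature table per subject. Regional feature means
#' follow smooth profiles along an arbitrary 1-D region ordering; AD subjects'
#' means are shifted by `effect_map` (standardized units; the noise SD is 1);
#' sites contribute additive feature offsets (and optional noise-scale
#' factors); subject covariates (age, sex, education) are drawn from the
#' spec's distributions. Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `features` (list of regions x 5 matrices, one per
#'   subject, named by subject id) and `metadata` (data.frame: subject_id,
#'   group, age, sex, education, site).
#' @export
generate_cohort <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n_ad <- spec$n_per_group[["AD"]]
  n_nc <- spec$n_per_group[["NC"]]
  n_sub <- n_ad + n_nc
  mu <- region_mean_profiles(spec$n_regions, spec$n_features)

  with_seed(spec$seed, {
    group <- c(rep("AD", n_ad), rep("NC", n_nc))
    site <- sample(rep_len(seq_len(spec$n_sites), n_sub))
    age <- pmin(pmax(rnorm(n_sub, spec$covariates$age[1],
                           spec$covariates$age[2]), 55), 95)
    sex <- rbinom(n_sub, 1, spec$covariates$p_female)
    education <- pmin(pmax(rnorm(n_sub, spec$covariates$education[1],
                                 spec$covariates$education[2]), 6), 22)
    subject_id <- sprintf("sub-%03d", seq_len(n_sub))

    features <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      x <- mu + spec$site_scale[site[s]] *
        matrix(rnorm(spec$n_regions * spec$n_features),
               spec$n_regions, spec$n_features)
      if (group[s] == "AD") x <- x + spec$effect_map
      x <- sweep(x, 2, spec$site_offsets[site[s], ], "+")
      dimnames(x) <- list(sprintf("region_%04d", seq_len(spec$n_regions)),
                          MSN_FEATURES)
      features[[s]] <- x
    }
    names(features) <- subject_id
    list(features = features,
         metadata = data.frame(subject_id = subject_id, group = group,
                               age = age, sex = sex, education = education,
                               site = factor(site),
                               stringsAsFactors = FALSE))
  })
}

#' Generate an atlas labeling for the synthetic parcellation
#'
#' Assigns each region one of the seven Von Economo cytoarchitectonic classes
#' and one of the seven Yeo resting-state networks. By default classes occupy
#' contiguous blocks of the region ordering (so the smooth feature profiles
#' give classes coherent gradient values) while networks cycle in shorter
#' interleaved blocks; `shuffle = TRUE` permutes both labelings.
#'
#' @param n_regions number of regions.
#' @param shuffle permute the labels randomly?
#' @param seed RNG seed (used only when `shuffle = TRUE`).
#' @return data.frame with columns region_id, econo_class, yeo_network.
#' @export
generate_atlas <- function(n_regions, shuffle = FALSE, seed = 1L) {
  stop_if(!is_count(n_regions) || n_regions < 7,
          "`n_regions` must be an integer >= 7")
  classes <- VON_ECONOMO_CLASSES[ceiling(seq_len(n_regions) / (n_regions / 7))]
  block <- max(1L, floor(n_regions / 21))
  networks <- YEO_NETWORKS[(ceiling(seq_len(n_regions) / block) - 1L) %% 7L + 1L]
  if (shuffle) {
    with_seed(seed, {
      classes <- sample(classes)
      networks <- sample(networks)
    })
  }
  data.frame(region_id = sprintf("region_%04d", seq_len(n_regions)),
             econo_class = factor(classes, levels = VON_ECONOMO_CLASSES),
             yeo_network = factor(networks, levels = YEO_NETWORKS),
             stringsAsFactors = FALSE)
}

#' Generate cognition scores coupled to class-mean gradients
#'
#' Each of the five scores (MMSE, ADNI-MEM, ADNI-EF, ADNI-VS, ADNI-LAN) is a
#' linear combination of per-subject class-mean gradient values plus Gaussian
#' noise. The generating weights are returned so recovery tests can compare
#' estimated against planted couplings.
#'
#' @param gradient_class_means subject x class numeric matrix.
#' @param coupling class x 5 weight matrix, or a vector of length
#'   `ncol(gradient_class_means)` recycled across the five scores.
#' @param noise_sd non-negative Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with `scores` (subject x 5 data.frame: MMSE, MEM, EF, VS,
#'   LAN) and `weights` (class x 5 matrix actually used).
#' @export
generate_cognition <- function(gradient_class_means, coupling,
                               noise_sd = 0.5, seed = 1L) {
  check_matrix(gradient_class_means, "gradient_class_means")
  score_names <- c("MMSE", "MEM", "EF", "VS", "LAN")
  if (is.vector(coupling)) {
    stop_if(length(coupling) != ncol(gradient_class_means),
            "`coupling` vector must have one weight per class")
    coupling <- matrix(coupling, ncol(gradient_class_means), 5L)
  }
  stop_if(!all(is.finite(coupling)), "coupling weights must be finite")
  stop_if(nrow(coupling) != ncol(gradient_class_means) || ncol(coupling) != 5L,
          "`coupling` must be a class x 5 matrix")
  stop_if(noise_sd < 0, "`noise_sd` must be non-negative")
  colnames(coupling) <- score_names
  n <- nrow(gradient_class_means)
  scores <- with_seed(seed, {
    gradient_class_means %*% coupling +
      matrix(rnorm(n * 5L, sd = noise_sd), n, 5L)
  })
  scores <- as.data.frame(scores)
  names(scores) <- score_names
  if (!is.null(rownames(gradient_class_means))) {
    scores <- cbind(subject_id = rownames(gradient_class_means), scores,
                    stringsAsFactors = FALSE)
  }
  list(scores = scores, weights = coupling)
}

#' Generate a synthetic regional gene-expression matrix
#'
#' Stands in for an atlas-mapped microarray expression matrix
#' (regions x genes). A designated subset of "planted" genes is constructed by
#' Cholesky-style mixing of the (standardized) supplied region map with
#' independent Gaussian noise, so each planted gene has expected Pearson
#' correlation `planted_corr` with the map; remaining genes are independent
#' noise.
#'
#' @param region_map numeric region vector the planted genes track (e.g. a
#'   group-difference t-map).
#' @param n_genes total genes.
#' @param n_planted number of planted genes (first `n_planted` columns).
#' @param planted_corr target correlation, strictly inside (-1, 1).
#' @param seed RNG seed.
#' @return list with `expression` (regions x genes matrix, planted genes named
#'   `planted_###`, others `noise_###`) and `planted` (planted gene names).
#' @export
generate_expression <- function(region_map, n_genes = 2000, n_planted = 50,
                                planted_corr = 0.9, seed = 1L) {
  stop_if(!is.numeric(region_map) || anyNA(region_map),
          "`region_map` must be numeric without NA")
  stop_if(!is_count(n_genes), "`n_genes` must be a positive integer")
  stop_if(n_planted < 0 || n_planted > n_genes,
          "`n_planted` must lie in [0, n_genes]")
  stop_if(abs(planted_corr) >= 1, "`planted_corr` must satisfy |corr| < 1")
  n <- length(region_map)
  stop_if(n < 3, "`region_map` needs at least 3 regions")
  if (n_planted > 0 && planted_corr != 0) {
    stop_if(sd(region_map) == 0,
            "constant `region_map`: correlation with planted genes undefined")
  }
  z <- if (sd(region_map) > 0) as.numeric(scale(region_map)) else region_map * 0
  with_seed(seed, {
    expr <- matrix(rnorm(n * n_genes), n, n_genes)
    if (n_planted > 0) {
      expr[, seq_len(n_planted)] <- planted_corr * z +
        sqrt(1 - planted_corr^2) * expr[, seq_len(n_planted), drop = FALSE]
    }
    gene_names <- c(if (n_planted > 0) sprintf("planted_%03d", seq_len(n_planted)),
                    if (n_genes > n_planted)
                      sprintf("noise_%04d", seq_len(n_genes - n_planted)))
    dimnames(expr) <- list(names(region_map) %||%
                             sprintf("region_%04d", seq_len(n)),
                           gene_names)
    list(expression = expr,
         planted = head(gene_names, n_planted))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic dataset to disk
#'
#' Writes one TSV feature table per subject, a metadata table, an atlas table,
#' an expression table, and a YAML manifest recording the spec and seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @param atlas optional [generate_atlas()] table.
#' @param expression optional [generate_expression()] result.
#' @param spec the [cohort_spec()] used (recorded in the manifest).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, atlas = NULL, expression = NULL,
                         spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub_dir <- file.path(dir, "features")
  dir.create(sub_dir, showWarnings = FALSE)
  for (id in names(cohort$features)) {
    tab <- data.frame(region_id = rownames(cohort$features[[id]]),
                      cohort$features[[id]], check.names = FALSE)
    write.table(tab, file.path(sub_dir, paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(atlas)) {
    write.table(atlas, file.path(dir, "atlas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(expression)) {
    tab <- data.frame(region_id = rownames(expression$expression),
                      expression$expression, check.names = FALSE)
    write.table(tab, file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(generator = "msngrad::write_cohort",
                   n_subjects = length(cohort$features),
                   seed = if (!is.null(spec)) spec$seed,
                   spec = if (!is.null(spec))
                     lapply(unclass(spec)[c("n_regions", "n_per_group",
                                            "n_sites", "seed")], as.vector))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
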