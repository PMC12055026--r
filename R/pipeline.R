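#' Assemble a pipeline configuration
#'
#' All tunables of the end-to-end run in one validated list. Unknown names
#' are rejected. Defaults give the desk-scale demo: a two-site cohort of 120
#' subjects and 400 regions with region effects drawn from N(0, 0.5^2),
#' 10%-density sparsification, 10 diffusion components at alpha 0.5, nested
#' 5-fold SVR, and paper-scale permutation/bootstrap counts (reduce
#' `n_perm_pls` / `n_boot` for quick runs).
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `msn_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_regions = 400L,
    n_per_group = c(AD = 60, NC = 60),
    n_sites = 2L,
    effect_sd = 0.5,
    site_offset = 0.3,
    density = 0.10,
    k = 10L,
    alpha = 0.5,
    diffusion_time = 0,
    covariates = c("age", "sex", "education"),
    graph_density = 0.10,
    coupling = c(prim_sens = -1, sec_sens = -0.5, asso1 = 1, asso2 = 0.5,
                 limbic = 0, prim_motor = 0, insula = 0),
    cognition_noise_sd = 1,
    n_outer = 5L,
    n_inner = 5L,
    svr_grid = svr_default_grid(),
    n_perm_cognition = 1000L,
    n_genes = 2000L,
    n_planted = 50L,
    planted_corr = 0.9,
    n_perm_pls = 10000L,
    n_boot = 10000L,
    q_gene = 0.001,
    stages = c(simulate = TRUE, msn = TRUE, gradients = TRUE, stats = TRUE,
               graph = TRUE, cognition = TRUE, pls = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  stop_if(length(unknown) > 0,
          sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, overrides)
  stop_if(cfg$density <= 0 || cfg$density >= 1, "`density` must lie in (0,1)")
  stop_if(!is_count(cfg$k), "`k` must be a positive integer")
  stop_if(!all(names(defaults$stages) %in% names(cfg$stages)),
          "`stages` must name every stage")
  class(cfg) <- "msn_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return validated `msn_config`.
#' @export
read_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  if (!is.null(raw$n_per_group)) raw$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$coupling)) raw$coupling <- unlist(raw$coupling)
  do.call(pipeline_config, raw)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full MSN-gradient pipeline
#'
#' Executes, in order: synthetic cohort generation, MSN construction,
#' template building and gradient alignment, site harmonization and group
#' contrasts (regional, class, network, plus KS distribution tests), graph
#' topology, cognition correlation/prediction, and the PLS1
#' transcription-neuroimaging association. Every artifact is written as TSV
#' under `out_dir` and listed, with md5 content hashes, in
#' `manifest.yaml` together with the config and seed, so a rerun with the
#' same config is bit-identical and every output is re-derivable from the
#' manifest alone. Stage toggles in `config$stages` skip stages; a stage
#' whose inputs were skipped aborts with the stage name.
#'
#' @param config an `msn_config` from [pipeline_config()] or a YAML path.
#' @param out_dir output directory (created).
#' @return invisibly, a list with all in-memory stage results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  stop_if(!inherits(config, "msn_config"), "`config` must be an msn_config")
  stop_if(missing(out_dir), "`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- config$stages
  results <- list(config = config)
  files <- character(0)
  need <- function(what, stage) {
    stop_if(is.null(results[[what]]),
            sprintf("stage `%s` needs output of a disabled stage (`%s`)",
                    stage, what))
    results[[what]]
  }

  if (isTRUE(on[["simulate"]])) {
    spec <- cohort_spec(
      n_regions = config$n_regions, n_per_group = config$n_per_group,
      n_sites = config$n_sites,
      effect_map = with_seed(derive_seed(config$seed, 11L),
                             rnorm(config$n_regions, 0, config$effect_sd)),
      site_offsets = seq(0, config$site_offset,
                         length.out = config$n_sites),
      seed = derive_seed(config$seed, 12L))
    cohort <- generate_cohort(spec)
    atlas <- generate_atlas(config$n_regions)
    results$spec <- spec
    results$cohort <- cohort
    results$atlas <- atlas
    files <- c(files, write_tsv(cohort$metadata,
                                file.path(out_dir, "metadata.tsv")),
               write_tsv(atlas, file.path(out_dir, "atlas.tsv")))
  }

  if (isTRUE(on[["msn"]])) {
    cohort <- need("cohort", "msn")
    msns <- lapply(cohort$features, function(f) compute_msn(zscore_features(f)))
    strength <- base::t(vapply(msns, regional_strength,
                               numeric(config$n_regions)))
    results$msns <- msns
    results$strength <- strength
    files <- c(files, write_tsv(
      data.frame(subject_id = rownames(strength), strength,
                 check.names = FALSE),
      file.path(out_dir, "regional_strength.tsv")))
  }

  if (isTRUE(on[["gradients"]])) {
    msns <- need("msns", "gradients")
    template <- build_template(msns, density = config$density, k = config$k,
                               alpha = config$alpha,
                               t = config$diffusion_time)
    grads <- lapply(msns, function(m) {
      g <- diffusion_embed(normalized_angle_affinity(
        sparsify_rows(m, config$density)),
        k = config$k, alpha = config$alpha, t = config$diffusion_time)
      procrustes_align(g, template)
    })
    g1 <- base::t(vapply(grads, function(g) g$scores[, 1],
                         numeric(config$n_regions)))
    colnames(g1) <- rownames(template$scores)
    globals <- do.call(rbind, lapply(names(grads), function(id) {
      m <- gradient_global_metrics(grads[[id]])
      data.frame(subject_id = id, explained_ratio_1 = m$explained_ratio_1,
                 range_1 = m$range_1, variance_1 = m$variance_1,
                 stringsAsFactors = FALSE)
    }))
    results$template <- template
    results$gradients <- grads
    results$g1 <- g1
    results$globals <- globals
    long <- data.frame(subject_id = rep(rownames(g1), each = ncol(g1)),
                       region_id = rep(colnames(g1), nrow(g1)),
                       g1 = as.numeric(base::t(g1)),
                       stringsAsFactors = FALSE)
    files <- c(files,
               write_tsv(long, file.path(out_dir, "gradient1.tsv")),
               write_tsv(globals, file.path(out_dir, "gradient_globals.tsv")),
               write_tsv(data.frame(component = seq_along(template$lambdas),
                                    lambda = template$lambdas),
                         file.path(out_dir, "template_lambdas.tsv")))
  }

  if (isTRUE(on[["stats"]])) {
    g1 <- need("g1", "stats")
    cohort <- need("cohort", "stats")
    atlas <- need("atlas", "stats")
    harmonized <- combat_harmonize(g1, cohort$metadata)
    stat_map <- glm_contrast(harmonized, cohort$metadata,
                             covariates = config$covariates)
    class_means <- aggregate_by_label(harmonized, atlas, "class")
    network_means <- aggregate_by_label(harmonized, atlas, "network")
    class_stats <- glm_contrast(class_means, cohort$metadata,
                                covariates = config$covariates)
    network_stats <- glm_contrast(network_means, cohort$metadata,
                                  covariates = config$covariates)
    ks <- ks_by_class(harmonized, cohort$metadata$group, atlas, "class")
    results$harmonized <- harmonized
    results$stat_map <- stat_map
    results$class_means <- class_means
    results$network_means <- network_means
    results$class_stats <- class_stats
    results$network_stats <- network_stats
    results$ks <- ks
    files <- c(files,
               write_tsv(stat_map, file.path(out_dir, "stat_map.tsv")),
               write_tsv(class_stats, file.path(out_dir, "class_stats.tsv")),
               write_tsv(network_stats,
                         file.path(out_dir, "network_stats.tsv")),
               write_tsv(ks, file.path(out_dir, "ks_tests.tsv")))
  }

  if (isTRUE(on[["graph"]])) {
    msns <- need("msns", "graph")
    cohort <- need("cohort", "graph")
    topo <- topology_metrics(msns, density = config$graph_density)
    globals <- need("globals", "graph")
    is_ad <- cohort$metadata$group == "AD"
    assoc <- topology_gradient_correlation(topo$path_length,
                                           globals$explained_ratio_1,
                                           subset = is_ad)
    results$topology <- topo
    results$topology_assoc <- assoc
    files <- c(files,
               write_tsv(topo, file.path(out_dir, "topology.tsv")),
               write_tsv(data.frame(metric = "path_length_vs_explained_ratio",
                                    r = assoc$r, p = assoc$p),
                         file.path(out_dir, "topology_assoc.tsv")))
  }

  if (isTRUE(on[["cognition"]])) {
    class_means <- need("class_means", "cognition")
    cohort <- need("cohort", "cognition")
    g1 <- need("harmonized", "cognition")
    strength <- need("strength", "cognition")
    # couple scores to standardized class means so signal and noise are on
    # comparable scales
    cm_std <- base::scale(class_means)
    cog <- generate_cognition(cm_std, config$coupling,
                              noise_sd = config$cognition_noise_sd,
                              seed = derive_seed(config$seed, 31L))
    is_ad <- cohort$metadata$group == "AD"
    covs <- as.matrix(cohort$metadata[is_ad, c("age", "sex", "education")])
    pc <- do.call(rbind, lapply(colnames(class_means), function(cl) {
      do.call(rbind, lapply(c("MMSE", "MEM", "EF", "VS", "LAN"), function(sc) {
        r <- partial_correlation(class_means[is_ad, cl],
                                 cog$scores[[sc]][is_ad], covs)
        data.frame(class = cl, score = sc, r = r$r, p = r$p,
                   stringsAsFactors = FALSE)
      }))
    }))
    pc$q <- stats::ave(pc$p, pc$score, FUN = bh_fdr)
    pred <- compare_feature_sets(
      g1[is_ad, , drop = FALSE], strength[is_ad, , drop = FALSE],
      as.list(cog$scores[is_ad, c("MMSE", "MEM", "EF", "VS", "LAN")]),
      n_perm = 0, seed = derive_seed(config$seed, 32L),
      n_outer = config$n_outer, n_inner = config$n_inner,
      grid = config$svr_grid)
    results$cognition <- cog
    results$partial_cor <- pc
    results$prediction <- pred
    files <- c(files,
               write_tsv(cbind(subject_id = cohort$metadata$subject_id,
                               cog$scores[setdiff(names(cog$scores),
                                                  "subject_id")]),
                         file.path(out_dir, "cognition.tsv")),
               write_tsv(pc, file.path(out_dir, "partial_correlations.tsv")),
               write_tsv(pred, file.path(out_dir, "prediction.tsv")))
  }

  if (isTRUE(on[["pls"]])) {
    stat_map <- need("stat_map", "pls")
    expr <- generate_expression(stat_map$t, n_genes = config$n_genes,
                                n_planted = config$n_planted,
                                planted_corr = config$planted_corr,
                                seed = derive_seed(config$seed, 41L))
    fit <- pls1_fit(expr$expression, stat_map$t)
    perm <- perm_test_pls(fit, n_perm = config$n_perm_pls,
                          seed = derive_seed(config$seed, 42L))
    genes <- bootstrap_gene_z(fit, n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 43L))
    sets <- select_gene_sets(genes, config$q_gene)
    genes$set <- ifelse(genes$gene %in% sets$genes_plus$gene, "+",
                        ifelse(genes$gene %in% sets$genes_minus$gene, "-", "ns"))
    results$expression <- expr
    results$pls <- fit
    results$pls_perm <- perm
    results$gene_table <- genes
    results$gene_sets <- sets
    files <- c(files,
               write_tsv(genes, file.path(out_dir, "pls_genes.tsv")),
               write_tsv(data.frame(region_id = stat_map$region_id,
                                    pls1_score = fit$scores, t = stat_map$t),
                         file.path(out_dir, "pls_scores.tsv")),
               write_tsv(data.frame(var_explained = fit$var_explained,
                                    r = fit$r, perm_p_var = perm$perm_p_var,
                                    perm_p_corr = perm$perm_p_corr),
                         file.path(out_dir, "pls_summary.tsv")))
  }

  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  manifest <- list(package = "msngrad",
                   version = as.character(utils::packageVersion("msngrad")),
                   seed = config$seed,
                   stages = as.list(config$stages),
                   config = config_for_manifest(config),
                   files = hashes)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  results$manifest_path <- manifest_path
  invisible(results)
}

config_for_manifest <- function(cfg) {
  keep <- setdiff(names(cfg), c("svr_grid", "stages"))
  out <- lapply(unclass(cfg)[keep], function(x) {
    if (is.numeric(x) || is.character(x) || is.logical(x)) as.vector(x) else NULL
  })
  out[!vapply(out, is.null, logical(1))]
}
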