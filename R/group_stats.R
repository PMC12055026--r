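#' Harmonize site effects with ComBat
#'
#' Parametric empirical-Bayes location/scale harmonization of a subject x
#' region value matrix across acquisition sites, protecting the biological
#' covariates (group, age, sex, education): values are standardized on the
#' covariate-including model, per-site location and scale estimates are shrunk
#' toward their empirical priors and removed, and the covariate effects are
#' restored. Delegates to the parametric ComBat of the sva package. With a
#' single site the input is returned unchanged.
#'
#' @param values subject x region numeric matrix.
#' @param design data.frame with columns subject_id, group, age, sex,
#'   education, site (rows aligned to `values`).
#' @return harmonized subject x region matrix.
#' @export
combat_harmonize <- function(values, design) {
  check_matrix(values, "values")
  design <- check_design(design, nrow(values))
  site <- factor(design$site)
  if (nlevels(site) < 2) return(values)
  counts <- table(site)
  stop_if(any(counts < 2),
          sprintf("site(s) with a single subject: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  mod <- model.matrix(~ group + age + sex + education, data = design)
  stop_if(qr(mod)$rank < ncol(mod), "rank-deficient covariate design")
  # sva::ComBat expects features (regions) x samples; silence its progress cat()s
  quiet <- utils::capture.output(
    out <- suppressMessages(
      sva::ComBat(dat = base::t(values), batch = site, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE)))
  harmonized <- base::t(out)
  dimnames(harmonized) <- dimnames(values)
  harmonized
}

check_design <- function(design, n) {
  stop_if(!is.data.frame(design), "`design` must be a data.frame")
  needed <- c("group", "age", "sex", "education", "site")
  missing_cols <- setdiff(needed, names(design))
  stop_if(length(missing_cols) > 0,
          sprintf("design lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  stop_if(nrow(design) != n, "design rows must match the value matrix")
  stop_if(anyNA(design[needed]), "design covariates contain missing values")
  design$group <- factor(design$group)
  stop_if(nlevels(design$group) != 2, "`group` must have exactly 2 levels")
  stop_if(any(table(design$group) < 2), "need >= 2 subjects per group")
  design
}

#' Region-wise GLM contrast of AD vs NC
#'
#' Fits, per region, an ordinary least-squares model of the value on group
#' plus the nuisance covariates (age, sex, education by default), and reports
#' the group coefficient's t statistic (AD minus NC direction), its two-sided
#' p from the t distribution with residual degrees of freedom, and
#' Benjamini-Hochberg q across regions. Fitting is vectorized: one design
#' decomposition serves all regions.
#'
#' @param values subject x region matrix (typically harmonized gradient-1
#'   scores).
#' @param design see [combat_harmonize()]. The first factor level of `group`
#'   is the reference; the contrast reported is `AD - NC` whenever the levels
#'   are named AD/NC, otherwise second level minus first.
#' @param covariates character vector of design columns to adjust for;
#'   default `c("age", "sex", "education")`. Use `character(0)` for the plain
#'   two-sample contrast.
#' @return data.frame: region_id, t, p, q (one row per region).
#' @export
glm_contrast <- function(values, design,
                         covariates = c("age", "sex", "education")) {
  check_matrix(values, "values")
  design <- check_design(design, nrow(values))
  grp <- design$group
  if (all(c("AD", "NC") %in% levels(grp))) {
    grp <- stats::relevel(grp, ref = "NC")   # coefficient = AD - NC
  }
  x <- cbind(`(Intercept)` = 1, group = as.numeric(grp) - 1)
  for (cv in covariates) {
    stop_if(!cv %in% names(design),
            sprintf("covariate `%s` not in design", cv))
    x <- cbind(x, as.numeric(design[[cv]]))
    colnames(x)[ncol(x)] <- cv
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop(sprintf("collinear design column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(x)
  df <- n - ncol(x)
  stop_if(df < 1, "no residual degrees of freedom")
  xtx_inv <- chol2inv(qr.R(qr_x))
  beta <- qr.coef(qr_x, values)
  resid <- values - x %*% beta
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tstat <- ifelse(se > 0, beta[2, ] / se, 0)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(region_id = colnames(values) %||%
               sprintf("region_%04d", seq_len(ncol(values))),
             t = as.numeric(tstat), p = as.numeric(p),
             q = bh_fdr(as.numeric(p)),
             stringsAsFactors = FALSE)
}

#' Aggregate regional values by atlas label
#'
#' Per subject, the arithmetic mean of the regional values over all regions
#' carrying each label (cytoarchitectonic class or functional network): the
#' class-level gradient used for the class contrasts and the cognition
#' correlations.
#'
#' @param values subject x region matrix; columns aligned to `atlas` rows.
#' @param atlas data.frame from [generate_atlas()] (or same layout).
#' @param level `"class"` (Von Economo) or `"network"` (Yeo).
#' @return subject x label matrix of means.
#' @export
aggregate_by_label <- function(values, atlas, level = c("class", "network")) {
  check_matrix(values, "values")
  level <- match.arg(level)
  col <- if (level == "class") "econo_class" else "yeo_network"
  stop_if(!col %in% names(atlas), sprintf("atlas lacks `%s`", col))
  labels <- if (is.factor(atlas[[col]])) atlas[[col]] else factor(atlas[[col]])
  stop_if(length(labels) != ncol(values),
          "atlas must label every region (column) of `values`")
  stop_if(any(table(labels) == 0),
          sprintf("empty label(s): %s",
                  paste(levels(labels)[table(labels) == 0], collapse = ", ")))
  out <- vapply(levels(labels), function(l) {
    rowMeans(values[, labels == l, drop = FALSE])
  }, numeric(nrow(values)))
  rownames(out) <- rownames(values)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' two-sided p is asymptotic. Used to compare pooled gradient-score
#' distributions between groups, globally and within each cytoarchitectonic
#' class.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(a, b) {
  stop_if(length(a) == 0 || length(b) == 0, "samples must be non-empty")
  stop_if(anyNA(a) || anyNA(b), "samples contain NA")
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Pool gradient values and KS-test each class
#'
#' Implements the default distributional contrast: within each label (plus a
#' `"global"` pseudo-label covering all regions), the per-subject regional
#' gradient values of each group are pooled and the pooled samples compared
#' by [ks_compare()]. Setting `pool = FALSE` compares per-subject label means
#' instead.
#'
#' @param values subject x region matrix.
#' @param group factor/character of group membership per subject.
#' @param atlas atlas table; `NULL` for global only.
#' @param level `"class"` or `"network"`.
#' @param pool pool regional values (default) or use per-subject means.
#' @return data.frame: label, D, p, q.
#' @export
ks_by_class <- function(values, group, atlas = NULL, level = "class",
                        pool = TRUE) {
  check_matrix(values, "values")
  group <- factor(group)
  stop_if(nlevels(group) != 2, "`group` must have 2 levels")
  g1 <- group == levels(group)[1]
  sets <- list(global = seq_len(ncol(values)))
  if (!is.null(atlas)) {
    col <- if (level == "class") "econo_class" else "yeo_network"
    labels <- factor(atlas[[col]])
    for (l in levels(labels)) sets[[l]] <- which(labels == l)
  }
  rows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    if (pool) {
      a <- as.numeric(values[g1, idx, drop = FALSE])
      b <- as.numeric(values[!g1, idx, drop = FALSE])
    } else {
      a <- rowMeans(values[g1, idx, drop = FALSE])
      b <- rowMeans(values[!g1, idx, drop = FALSE])
    }
    r <- ks_compare(a, b)
    data.frame(label = nm, D = r$D, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1 (the `p.adjust` BH procedure). Applied within each test family
#' separately (regions; classes; networks).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  stop_if(!is.numeric(p) || anyNA(p), "`p` must be numeric without NA")
  stop_if(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
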