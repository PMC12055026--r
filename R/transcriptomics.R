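#' First partial-least-squares component of expression against a t-map
#'
#' Univariate-response PLS: with X the per-gene z-scored regional expression
#' and y the centered regional t-map, the first-component weight vector is
#' the normalized covariance direction `w = X'y / ||X'y||`, the region scores
#' are `X w`, and the explained variance is the R-squared of y regressed on
#' the scores. For a single response this first component is mathematically
#' identical across the standard PLS variants (NIPALS, SIMPLS). Orientation
#' is fixed so that `cor(scores, y) >= 0`; flipping the sign of y flips
#' scores and weights exactly.
#'
#' @param X regions x genes matrix. Zero-variance genes are dropped with a
#'   message; remaining genes are z-scored across regions unless
#'   `scale = FALSE`.
#' @param y numeric regional response (e.g. the group-contrast t map);
#'   centered internally.
#' @param scale z-score genes across regions first (default TRUE).
#' @return list of class `pls1`: `scores` (region vector), `weights`
#'   (per-gene), `var_explained`, `r` (cor of scores with y), `genes`
#'   (retained gene names), `y` (centered response), `X` (processed matrix).
#' @export
pls1_fit <- function(X, y, scale = TRUE) {
  check_matrix(X, "X")
  stop_if(nrow(X) < 10, "need at least 10 regions")
  stop_if(length(y) != nrow(X), "`y` must have one value per region")
  stop_if(anyNA(y), "`y` contains NA")
  stop_if(sd(y) == 0, "constant response: PLS undefined")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    message(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (scale) X <- base::scale(X)
  else X <- base::scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  stop_if(nw == 0, "response orthogonal to every gene: zero weight vector")
  w <- w / nw
  scores <- drop(X %*% w)
  r <- cor(scores, yc)
  if (r < 0) {
    w <- -w
    scores <- -scores
    r <- -r
  }
  structure(list(scores = scores, weights = w, var_explained = r^2, r = r,
                 genes = colnames(X), y = yc, X = X),
            class = "pls1")
}

#' Permutation significance of the PLS1 association
#'
#' Region labels of the response are shuffled `n_perm` times; the explained
#' variance and the absolute score-response correlation are recomputed per
#' shuffle, and each observed statistic gets
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`. Plain region shuffling is
#' used (no spatial-autocorrelation-preserving surrogate); supply
#' `null_maps` to override with user-generated null responses.
#'
#' @param fit a `pls1` object.
#' @param n_perm number of permutations (default 10000; tests use fewer).
#' @param seed RNG seed.
#' @param null_maps optional matrix (regions x n_perm) of pre-built null
#'   responses replacing the shuffles.
#' @return list: `perm_p_var`, `perm_p_corr`, `var_perm` (null explained
#'   variances).
#' @export
perm_test_pls <- function(fit, n_perm = 10000, seed = 1L, null_maps = NULL) {
  stop_if(!inherits(fit, "pls1"), "`fit` must come from pls1_fit()")
  stop_if(!is_count(n_perm), "`n_perm` must be a positive integer")
  X <- fit$X
  var_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- if (is.null(null_maps)) sample(fit$y) else null_maps[, b]
      yp <- yp - mean(yp)
      w <- drop(crossprod(X, yp))
      nw <- sqrt(sum(w^2))
      if (nw == 0) return(0)
      cor(drop(X %*% (w / nw)), yp)^2
    }, numeric(1))
  })
  # var_explained is the squared score-response correlation, so the |r| null
  # is the square root of the variance null
  list(perm_p_var = (1 + sum(var_perm >= fit$var_explained)) / (1 + n_perm),
       perm_p_corr = (1 + sum(sqrt(var_perm) >= fit$r)) / (1 + n_perm),
       var_perm = var_perm)
}

#' Bootstrap z-scores of PLS1 gene weights
#'
#' Regions are resampled with replacement, PLS1 refit per resample, and each
#' replicate weight vector sign-aligned to the original (by the sign of its
#' inner product with the original weights) to prevent component-reflection
#' artifacts. The corrected weight of a gene is `z = w / SD_boot(w)`;
#' two-sided p-values use the standard normal reference and are BH-FDR
#' adjusted across genes.
#'
#' @param fit a `pls1` object.
#' @param n_boot bootstrap resamples (>= 100; default 10000, tests use
#'   fewer).
#' @param seed RNG seed.
#' @return data.frame: gene, weight, z, p, q.
#' @export
bootstrap_gene_z <- function(fit, n_boot = 10000, seed = 1L) {
  stop_if(!inherits(fit, "pls1"), "`fit` must come from pls1_fit()")
  stop_if(!is_count(n_boot) || n_boot < 100, "`n_boot` must be >= 100")
  X <- fit$X
  n <- nrow(X)
  redraws <- 0L
  boot_w <- with_seed(seed, {
    out <- matrix(NA_real_, length(fit$weights), n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- fit$y[idx]
        if (sd(yb) > 0) break
        redraws <- redraws + 1L
      }
      Xb <- X[idx, , drop = FALSE]
      Xb <- sweep(Xb, 2, colMeans(Xb))
      yb <- yb - mean(yb)
      w <- drop(crossprod(Xb, yb))
      nw <- sqrt(sum(w^2))
      if (nw > 0) w <- w / nw
      if (sum(w * fit$weights) < 0) w <- -w
      out[, b] <- w
    }
    out
  })
  if (redraws > 0) {
    message(sprintf("%d degenerate resample(s) redrawn", redraws))
  }
  se <- apply(boot_w, 1, sd)
  z <- ifelse(se > 0, fit$weights / se, 0)
  p <- 2 * pnorm(-abs(z))
  data.frame(gene = fit$genes %||% seq_along(z), weight = fit$weights,
             z = z, p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Select significantly contributing gene sets
#'
#' Splits genes into a positive-weight and a negative-weight set at the
#' bootstrap-z FDR threshold (default q < 0.001), each ranked by descending
#' `|z|`. These ranked lists are the terminal output handed to external
#' enrichment portals.
#'
#' @param gene_table data.frame from [bootstrap_gene_z()].
#' @param q_threshold FDR cutoff (default 0.001).
#' @return list: `genes_plus`, `genes_minus` (ranked data.frames), disjoint.
#' @export
select_gene_sets <- function(gene_table, q_threshold = 0.001) {
  stop_if(!all(c("gene", "z", "q") %in% names(gene_table)),
          "`gene_table` must have gene, z, q columns")
  sig <- gene_table[gene_table$q < q_threshold, , drop = FALSE]
  plus <- sig[sig$z > 0, , drop = FALSE]
  minus <- sig[sig$z < 0, , drop = FALSE]
  list(genes_plus = plus[order(-abs(plus$z)), , drop = FALSE],
       genes_minus = minus[order(-abs(minus$z)), , drop = FALSE])
}
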