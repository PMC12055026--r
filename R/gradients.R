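#' Row-wise sparsification of an MSN
#'
#' Per row, only the `floor(density * n)` largest entries by signed value are
#' retained; everything else (including the zero diagonal) is set to 0. The
#' result is generally asymmetric — symmetry is restored downstream by the
#' cosine-similarity construction. Signed-value (not absolute) selection is
#' the standard gradient-workflow convention; negative survivors are rare at
#' 10% density.
#'
#' @param msn symmetric regions x regions MSN matrix.
#' @param density fraction of entries kept per row, in (0, 1). Default 0.10.
#' @return row-sparse matrix of the same shape.
#' @export
sparsify_rows <- function(msn, density = 0.10) {
  check_square_symmetric(msn, "msn")
  stop_if(density <= 0 || density >= 1, "`density` must lie in (0, 1)")
  n <- nrow(msn)
  k <- floor(density * n)
  stop_if(k < 1, sprintf("density %.3f keeps 0 of %d entries per row", density, n))
  out <- matrix(0, n, n, dimnames = dimnames(msn))
  for (i in seq_len(n)) {
    row <- msn[i, ]
    row[i] <- -Inf                  # diagonal never competes for selection
    keep <- order(row, decreasing = TRUE)[seq_len(k)]
    out[i, keep] <- msn[i, keep]
  }
  out
}

#' Normalized-angle affinity between sparsified connectivity profiles
#'
#' Computes the cosine similarity between every pair of (full-length,
#' zero-padded) sparsified rows and maps it through the normalized-angle
#' transform `1 - acos(cos_ij) / pi`, yielding a symmetric affinity in
#' \[0, 1\]: identical profiles give 1, orthogonal 0.5, antiparallel 0.
#' Cosines are clamped into \[-1, 1\] before `acos` to absorb floating-point
#' overshoot.
#'
#' @param sparse row-sparse matrix from [sparsify_rows()].
#' @return symmetric regions x regions affinity matrix, unit diagonal.
#' @export
normalized_angle_affinity <- function(sparse) {
  check_matrix(sparse, "sparse")
  stop_if(nrow(sparse) != ncol(sparse), "`sparse` must be square")
  norms <- sqrt(rowSums(sparse^2))
  if (any(norms == 0)) {
    stop(sprintf("all-zero row(s) %s: cosine similarity undefined",
                 paste(which(norms == 0), collapse = ", ")), call. = FALSE)
  }
  cosine <- tcrossprod(sparse / norms)
  cosine <- pmin(pmax(cosine, -1), 1)
  aff <- 1 - acos(cosine) / pi
  (aff + t(aff)) / 2
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Standard diffusion-map construction (anisotropic alpha-normalization of
#' the kernel, row-stochastic transition operator, eigendecomposition via the
#' symmetric conjugate): components are ordered by descending eigenvalue
#' magnitude after dropping the trivial constant component, and at diffusion
#' time 0 each component is scaled by `lambda / (1 - lambda)`. Explained
#' variance fractions are the positive parts of the nontrivial eigenvalues
#' over their total across the full spectrum, so they are non-negative,
#' non-increasing, and sum to at most 1.
#'
#' @param affinity symmetric non-negative affinity matrix whose graph is
#'   connected.
#' @param k number of components to return (default 10).
#' @param alpha anisotropic-diffusion normalization exponent in \[0, 1\]
#'   (default 0.5, the density-corrected Fokker-Planck variant).
#' @param t diffusion time; 0 selects the automatic `lambda/(1-lambda)`
#'   scaling (default).
#' @return `gradient_set` list: `scores` (regions x k), `lambdas` (explained
#'   variance fractions), `eigenvalues` (raw nontrivial eigenvalues),
#'   `aligned` flag, `template_id`.
#' @export
diffusion_embed <- function(affinity, k = 10, alpha = 0.5, t = 0) {
  check_square_symmetric(affinity, "affinity")
  stop_if(any(affinity < 0), "`affinity` must be non-negative")
  n <- nrow(affinity)
  stop_if(!is_count(k) || k >= n, "`k` must be a positive integer < n_regions")
  stop_if(alpha < 0 || alpha > 1, "`alpha` must lie in [0, 1]")
  comp <- connected_components(affinity > 0)
  stop_if(max(comp) > 1,
          sprintf("affinity graph is disconnected (%d components)", max(comp)))

  d <- rowSums(affinity)
  w <- affinity / outer(d^alpha, d^alpha)      # alpha-normalized kernel
  d1 <- rowSums(w)
  inv_sqrt <- 1 / sqrt(d1)
  m <- w * outer(inv_sqrt, inv_sqrt)           # symmetric conjugate of D^-1 W
  m <- (m + base::t(m)) / 2                    # param `t` shadows base::t here
  eig <- eigen(m, symmetric = TRUE)

  ord <- order(abs(eig$values), decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # right eigenvectors of the transition operator; the leading one is the
  # stationary direction, used to normalize the others to the constant-1 gauge
  psi <- vecs * inv_sqrt
  psi <- psi / psi[, 1]
  vals_nt <- vals[-1]
  psi_nt <- psi[, -1, drop = FALSE]

  pos <- pmax(vals_nt, 0)
  fractions <- if (sum(pos) > 0) pos / sum(pos) else pos
  scale_fac <- if (t == 0) vals_nt / (1 - vals_nt) else vals_nt^t
  scores <- psi_nt[, seq_len(k), drop = FALSE] *
    rep(scale_fac[seq_len(k)], each = n)
  degenerate <- all(abs(vals_nt[seq_len(k)]) < 1e-12)
  if (degenerate) scores[] <- 0
  rownames(scores) <- rownames(affinity)
  colnames(scores) <- paste0("g", seq_len(k))
  structure(list(scores = scores,
                 lambdas = fractions[seq_len(k)],
                 eigenvalues = vals_nt[seq_len(k)],
                 degenerate = degenerate,
                 aligned = FALSE,
                 template_id = NULL),
            class = "gradient_set")
}

# Connected components of a logical adjacency matrix (label vector).
connected_components <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  current <- 0L
  for (start in seq_len(n)) {
    if (labels[start] > 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- current
      queue <- c(queue, nb)
    }
  }
  labels
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d regions x %d components (%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$aligned) "aligned" else "unaligned"))
  cat(sprintf("  explained fractions: %s\n",
              paste(sprintf("%.3f", head(x$lambdas, 5)), collapse = " ")))
  invisible(x)
}

#' Build the cohort alignment template
#'
#' Averages all subjects' MSNs element-wise (both groups), then runs the same
#' sparsify / normalized-angle / diffusion-embed steps. The template's own
#' sign indeterminacy is fixed by requiring the region with the largest
#' absolute score on gradient 1 to be positive; every subject is then
#' Procrustes-aligned to this template, which resolves their sign/rotation
#' ambiguity consistently.
#'
#' @param msns list of >= 2 MSN matrices with identical region sets.
#' @inheritParams diffusion_embed
#' @param density row sparsification density.
#' @return an unaligned `gradient_set` serving as alignment target, with a
#'   `template_id` content hash.
#' @export
build_template <- function(msns, density = 0.10, k = 10, alpha = 0.5, t = 0) {
  stop_if(!is.list(msns) || length(msns) < 2, "need at least 2 MSNs")
  dims <- vapply(msns, nrow, integer(1))
  stop_if(length(unique(dims)) != 1, "MSNs have mismatched region sets")
  rn <- rownames(msns[[1]])
  for (m in msns) {
    stop_if(!identical(rownames(m), rn), "MSNs have mismatched region sets")
  }
  avg <- Reduce(`+`, msns) / length(msns)
  stop_if(max(abs(avg)) < 1e-12,
          "average MSN is (numerically) zero: degenerate template")
  g <- diffusion_embed(normalized_angle_affinity(sparsify_rows(avg, density)),
                       k = k, alpha = alpha, t = t)
  anchor <- which.max(abs(g$scores[, 1]))
  if (g$scores[anchor, 1] < 0) g$scores[, 1] <- -g$scores[, 1]
  tmp <- tempfile(fileext = ".rds")
  saveRDS(round(g$scores, 12), tmp)
  g$template_id <- unname(tools::md5sum(tmp))
  unlink(tmp)
  g
}

#' Procrustes-align a subject's gradients to a template
#'
#' Applies the orthogonal transform (rotation/reflection, no scaling or
#' translation) minimizing the Frobenius distance between the subject's
#' component matrix and the template's. Eigenvector sign and rotational
#' indeterminacy of the embedding are resolved this way; the per-component
#' explained-variance fractions are untouched.
#'
#' @param subject unaligned `gradient_set`.
#' @param template `gradient_set` from [build_template()] with the same
#'   number of regions and components.
#' @return the subject `gradient_set` with rotated scores, `aligned = TRUE`.
#' @export
procrustes_align <- function(subject, template) {
  stop_if(!inherits(subject, "gradient_set") ||
            !inherits(template, "gradient_set"),
          "`subject` and `template` must be gradient_set objects")
  s <- subject$scores
  tm <- template$scores
  stop_if(!all(dim(s) == dim(tm)),
          sprintf("dimension mismatch: subject %dx%d vs template %dx%d",
                  nrow(s), ncol(s), nrow(tm), ncol(tm)))
  sv <- svd(crossprod(s, tm))
  q <- sv$u %*% t(sv$v)
  subject$scores <- s %*% q
  dimnames(subject$scores) <- dimnames(s)
  subject$aligned <- TRUE
  subject$template_id <- template$template_id
  subject
}

#' Global metrics of the first gradient
#'
#' The three global summaries contrasted between groups: the fraction of MSN
#' variance explained by gradient 1, the range (max - min) of its regional
#' scores, and their variance (ddof = 1).
#'
#' @param g an aligned `gradient_set`.
#' @return list: `explained_ratio_1`, `range_1`, `variance_1`.
#' @export
gradient_global_metrics <- function(g) {
  stop_if(!inherits(g, "gradient_set"), "`g` must be a gradient_set")
  s1 <- g$scores[, 1]
  list(explained_ratio_1 = g$lambdas[1],
       range_1 = max(s1) - min(s1),
       variance_1 = var(s1))
}
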