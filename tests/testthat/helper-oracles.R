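# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain-loop formulas, dense general eigensolvers, exhaustive
# enumeration.

oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / (sqrt(sum(xc^2)) * sqrt(sum(yc^2)))
}

# Pooled-variance two-sample t (classical closed form).
oracle_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Two-sample KS D by sweeping the pooled breakpoints.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# BH step-up q-values: q_(k) = min_{i >= k} p_(i) * m / i, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i, 1)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# First PLS component by the iterative NIPALS recursion.
oracle_nipals_pls1 <- function(X, y, scale = TRUE) {
  X <- if (scale) base::scale(X) else base::scale(X, scale = FALSE)
  yc <- y - mean(y)
  u <- yc
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (iter in 1:200) {
    w_new <- drop(crossprod(X, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    tt <- drop(X %*% w_new)
    c_load <- sum(yc * tt) / sum(tt^2)
    u <- yc * 1      # univariate block: u stays proportional to y
    if (sum(abs(w_new - w)) < 1e-14) { w <- w_new; break }
    w <- w_new
  }
  tt <- drop(X %*% w)
  fitted <- tt * (sum(yc * tt) / sum(tt^2))
  list(w = w, scores = tt, var_explained = 1 - sum((yc - fitted)^2) / sum(yc^2))
}

# Diffusion-map scores via a general (non-symmetric) eigendecomposition of
# the row-stochastic operator itself.
oracle_diffusion_scores <- function(affinity, k, alpha = 0.5) {
  d <- rowSums(affinity)
  w <- affinity / outer(d^alpha, d^alpha)
  p <- w / rowSums(w)
  eig <- eigen(p)
  ord <- order(abs(Re(eig$values)), decreasing = TRUE)
  vals <- Re(eig$values[ord])
  vecs <- Re(eig$vectors[, ord, drop = FALSE])
  psi <- vecs / vecs[, 1]
  sc <- psi[, 2:(k + 1), drop = FALSE] *
    rep(vals[2:(k + 1)] / (1 - vals[2:(k + 1)]), each = nrow(p))
  sc
}

# Onnela weighted clustering by exhaustive triangle enumeration.
oracle_onnela_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  ci <- numeric(n)
  for (i in 1:n) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h && w[j, h] > 0) {
        s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# All-pairs shortest paths (Floyd-Warshall) on 1/weight lengths; mean over
# ordered pairs.
oracle_path_length <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  mean(d[row(d) != col(d)])
}

# Recursive partial-correlation formula for a single covariate.
oracle_partial_recursive1 <- function(x, y, z) {
  rxy <- oracle_pearson(x, y)
  rxz <- oracle_pearson(x, z)
  ryz <- oracle_pearson(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(k * k), k))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))), k)
}

# Random connected symmetric non-negative affinity (Gaussian kernel on
# random points), unit diagonal.
random_affinity <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  d2 <- as.matrix(dist(pts))^2
  exp(-d2 / median(d2))
}
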