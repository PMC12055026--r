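test_that("PLS1 weight direction is the normalized covariance with the response", {
  set.seed(1)
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 12), 40)
    colnames(X) <- paste0("g", 1:12)
    y <- rnorm(40)
    fit <- pls1_fit(X, y)
    w_direct <- drop(crossprod(scale(X), y - mean(y)))
    w_direct <- w_direct / sqrt(sum(w_direct^2))
    cosang <- abs(sum(fit$weights * w_direct))
    expect_gt(cosang, 1 - 1e-10)
    # NIPALS oracle agreement
    oracle <- oracle_nipals_pls1(X, y)
    expect_equal(fit$var_explained, oracle$var_explained, tolerance = 1e-10)
    expect_gt(abs(sum(fit$weights * oracle$w)), 1 - 1e-10)
  }
})

test_that("PLS1 landmarks: single-gene response and orthogonal response", {
  set.seed(2)
  g <- rnorm(30)
  X <- matrix(g, dimnames = list(NULL, "gene1"))
  fit <- pls1_fit(X, 2 * g)
  expect_equal(fit$var_explained, 1, tolerance = 1e-10)
  expect_gt(cor(fit$scores, g), 1 - 1e-10)
  # response orthogonalized against every gene column
  X2 <- matrix(rnorm(30 * 3), 30)
  y <- rnorm(30)
  y_orth <- residuals(lm(y ~ scale(X2)))
  fit0 <- pls1_fit(X2, y_orth)
  expect_lt(fit0$var_explained, 1e-10)
  expect_error(pls1_fit(X2, rep(3, 30)), "constant")
})

test_that("PLS1 is invariant to gene order and consistent region relabeling", {
  set.seed(3)
  X <- matrix(rnorm(50 * 20), 50); colnames(X) <- paste0("g", 1:20)
  y <- rnorm(50)
  fit <- pls1_fit(X, y)
  perm_g <- sample(20)
  fit_g <- pls1_fit(X[, perm_g], y)
  expect_equal(fit_g$var_explained, fit$var_explained, tolerance = 1e-12)
  expect_equal(unname(fit_g$weights), unname(fit$weights[perm_g]),
               tolerance = 1e-12)
  perm_r <- sample(50)
  fit_r <- pls1_fit(X[perm_r, ], y[perm_r])
  expect_equal(fit_r$var_explained, fit$var_explained, tolerance = 1e-12)
  expect_equal(fit_r$scores, fit$scores[perm_r], tolerance = 1e-10)
})

test_that("flipping the response sign flips scores and weights exactly", {
  set.seed(4)
  X <- matrix(rnorm(40 * 10), 40); colnames(X) <- paste0("g", 1:10)
  y <- drop(X[, 1] + rnorm(40, sd = 0.5))
  fit <- pls1_fit(X, y)
  fit_neg <- pls1_fit(X, -y)
  expect_gte(fit$r, 0)
  expect_gte(fit_neg$r, 0)          # orientation convention holds either way
  expect_equal(fit_neg$weights, -fit$weights, tolerance = 1e-12)
  expect_equal(fit_neg$scores, -fit$scores, tolerance = 1e-12)
})

test_that("permutation test flags planted signal and respects the p floor", {
  set.seed(5)
  map <- rnorm(100)
  ex <- generate_expression(map, n_genes = 120, n_planted = 15,
                            planted_corr = 0.9, seed = 6)
  fit <- pls1_fit(ex$expression, map)
  pp <- perm_test_pls(fit, n_perm = 99, seed = 7)
  expect_equal(pp$perm_p_var, 1 / 100)
  expect_equal(pp$perm_p_corr, 1 / 100)
  # null response: p must not be extreme
  fit0 <- pls1_fit(ex$expression[, 16:120], rnorm(100))
  pp0 <- perm_test_pls(fit0, n_perm = 99, seed = 8)
  expect_gt(pp0$perm_p_var, 0.01)
})

test_that("bootstrap z ranks a planted gene first and spares noise genes", {
  set.seed(6)
  map <- rnorm(120)
  X <- cbind(tracker = map + rnorm(120, sd = 0.1),
             matrix(rnorm(120 * 60), 120,
                    dimnames = list(NULL, paste0("noise_", 1:60))))
  fit <- pls1_fit(X, map)
  tab <- bootstrap_gene_z(fit, n_boot = 300, seed = 9)
  expect_equal(tab$gene[which.max(abs(tab$z))], "tracker")
  noise <- tab[tab$gene != "tracker", ]
  expect_lte(mean(noise$q < 0.001), 0.02)
  # duplicated gene columns get equal weights and near-equal z
  X2 <- cbind(a = map + rnorm(120, sd = 0.3), matrix(rnorm(120 * 10), 120))
  X2 <- cbind(X2, b = X2[, "a"])
  colnames(X2) <- c("a", paste0("n", 1:10), "b")
  fit2 <- pls1_fit(X2, map)
  expect_equal(unname(fit2$weights["a"]), unname(fit2$weights["b"]),
               tolerance = 1e-12)
  tab2 <- bootstrap_gene_z(fit2, n_boot = 300, seed = 10)
  za <- tab2$z[tab2$gene == "a"]; zb <- tab2$z[tab2$gene == "b"]
  expect_lt(abs(za - zb) / abs(za), 0.15)
})

test_that("gene-set selection is disjoint, thresholded, and antisymmetric", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    weight = c(1, -1, 2, -2, 0.1, -0.1),
                    z = c(5, -5, 8, -8, 0.5, -0.5),
                    q = c(1e-5, 1e-5, 1e-6, 1e-6, 0.5, 0.5))
  sets <- select_gene_sets(tab)
  expect_setequal(sets$genes_plus$gene, c("g1", "g3"))
  expect_setequal(sets$genes_minus$gene, c("g2", "g4"))
  expect_equal(sets$genes_plus$gene[1], "g3")     # ranked by |z|
  expect_length(intersect(sets$genes_plus$gene, sets$genes_minus$gene), 0)
  none <- select_gene_sets(transform(tab, q = 0.5))
  expect_equal(nrow(none$genes_plus), 0)
  expect_equal(nrow(none$genes_minus), 0)
  # flipping y swaps the sets
  set.seed(7)
  map <- rnorm(80)
  ex <- generate_expression(map, n_genes = 60, n_planted = 10,
                            planted_corr = 0.85, seed = 11)
  f1 <- pls1_fit(ex$expression, map)
  f2 <- pls1_fit(ex$expression, -map)
  s1 <- select_gene_sets(bootstrap_gene_z(f1, 300, seed = 12))
  s2 <- select_gene_sets(bootstrap_gene_z(f2, 300, seed = 12))
  expect_setequal(s1$genes_plus$gene, s2$genes_minus$gene)
})
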