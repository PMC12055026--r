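test_that("row sparsification keeps exactly the top entries per row", {
  msn <- random_msn(10, seed = 1)
  sp <- sparsify_rows(msn, 0.10)
  expect_true(all(rowSums(sp != 0) == 1))        # floor(0.1 * 10) = 1
  msn6 <- random_msn(6, seed = 2)
  sp6 <- sparsify_rows(msn6, 0.45)               # floor(2.7) = 2 per row
  for (i in 1:6) {
    top <- order(replace(msn6[i, ], i, -Inf), decreasing = TRUE)[1:2]
    expect_setequal(which(sp6[i, ] != 0), top)
    expect_equal(sp6[i, top], msn6[i, top])
  }
  expect_error(sparsify_rows(msn6, 0.01), "0 of 6")
  expect_error(sparsify_rows(msn6, 1.2), "density")
})

test_that("normalized-angle affinity maps cosine landmarks correctly", {
  rows <- rbind(c(1, 2, 0, 0), c(2, 4, 0, 0),       # parallel
                c(0, 0, 3, 0),                      # orthogonal to row 1
                c(-1, -2, 0, 0))                    # antiparallel to row 1
  aff <- normalized_angle_affinity(rows)
  expect_equal(aff[1, 2], 1)
  expect_equal(aff[1, 3], 0.5)
  expect_equal(aff[1, 4], 0)
  expect_true(all(aff >= 0 & aff <= 1))
  expect_lt(max(abs(aff - t(aff))), 1e-14)
  rows[3, ] <- 0
  expect_error(normalized_angle_affinity(rows), "3")
})

test_that("diffusion embedding matches a dense general-eigensolver oracle", {
  for (seed in c(1, 2, 3)) {
    n <- c(12, 25, 40)[seed]
    aff <- random_affinity(n, seed)
    k <- 5
    g <- diffusion_embed(aff, k = k)
    oracle <- oracle_diffusion_scores(aff, k)
    for (j in seq_len(k)) {
      cosang <- abs(sum(g$scores[, j] * oracle[, j])) /
        (sqrt(sum(g$scores[, j]^2)) * sqrt(sum(oracle[, j]^2)))
      expect_gt(cosang, 1 - 1e-8)
    }
  }
})

test_that("explained-variance fractions are a valid descending decomposition", {
  aff <- random_affinity(30, seed = 9)
  g <- diffusion_embed(aff, k = 8)
  expect_true(all(g$lambdas >= 0))
  expect_true(all(diff(g$lambdas) <= 1e-12))
  expect_lte(sum(g$lambdas), 1 + 1e-12)
})

test_that("gradient 1 separates two well-separated blocks by sign", {
  g <- diffusion_embed(block_affinity(3), k = 2)
  signs <- sign(g$scores[, 1])
  expect_true(all(signs[1:3] == signs[1]) && all(signs[4:6] == -signs[1]))
})

test_that("constant affinity yields degenerate (flagged, zero) gradients", {
  aff <- matrix(1, 8, 8)
  g <- diffusion_embed(aff, k = 3)
  expect_true(g$degenerate)
  expect_true(all(g$scores == 0))
})

test_that("disconnected or asymmetric affinities are rejected", {
  aff <- matrix(0, 6, 6)
  aff[1:3, 1:3] <- 0.9; aff[4:6, 4:6] <- 0.9; diag(aff) <- 1
  expect_error(diffusion_embed(aff, k = 2), "disconnected")
  bad <- random_affinity(8, 1); bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(diffusion_embed(bad, k = 2), "symmetric")
})

test_that("template from identical MSNs equals the single-subject embedding", {
  msn <- random_msn(30, seed = 4)
  tpl <- build_template(list(msn, msn, msn), k = 4)
  single <- diffusion_embed(normalized_angle_affinity(sparsify_rows(msn)),
                            k = 4)
  for (j in 1:4) {
    cosang <- abs(sum(tpl$scores[, j] * single$scores[, j])) /
      (sqrt(sum(tpl$scores[, j]^2)) * sqrt(sum(single$scores[, j]^2)))
    expect_gt(cosang, 1 - 1e-10)
  }
  expect_gt(tpl$scores[which.max(abs(tpl$scores[, 1])), 1], 0)
  expect_error(build_template(list(msn, -msn)), "degenerate")
  expect_error(build_template(list(msn, random_msn(20, 5))), "mismatched")
})

test_that("Procrustes alignment is exact on the solvable cases", {
  msn <- random_msn(40, seed = 6)
  tpl <- build_template(list(msn, random_msn(40, 7)), k = 5)
  # self-alignment: identity
  aligned <- procrustes_align(tpl, tpl)
  expect_equal(aligned$scores, tpl$scores, tolerance = 1e-10)
  # reflection of gradient 1 is restored
  flipped <- tpl
  flipped$scores[, 1] <- -flipped$scores[, 1]
  expect_equal(procrustes_align(flipped, tpl)$scores, tpl$scores,
               tolerance = 1e-8)
  # planted random orthogonal rotation recovered
  q <- random_orthogonal(5, seed = 8)
  rotated <- tpl
  rotated$scores <- tpl$scores %*% q
  back <- procrustes_align(rotated, tpl)
  expect_lt(max(abs(back$scores - tpl$scores)), 1e-8)
  # lambdas never change
  expect_identical(back$lambdas, tpl$lambdas)
  small <- tpl; small$scores <- small$scores[, 1:3]
  expect_error(procrustes_align(small, tpl), "mismatch")
})

test_that("global gradient metrics follow their closed forms", {
  g <- diffusion_embed(random_affinity(20, 10), k = 3)
  g$aligned <- TRUE
  m <- gradient_global_metrics(g)
  s1 <- g$scores[, 1]
  expect_equal(m$range_1, max(s1) - min(s1))
  expect_equal(m$variance_1, sum((s1 - mean(s1))^2) / (length(s1) - 1))
  expect_equal(m$explained_ratio_1, g$lambdas[1])
  g$scores[, 1] <- 0.3
  expect_equal(gradient_global_metrics(g)$range_1, 0)
  expect_equal(gradient_global_metrics(g)$variance_1, 0)
  g$scores[, 1] <- c(-1, 0, 1, rep(0, 17))
  expect_equal(gradient_global_metrics(g)$range_1, 2)
})

test_that("embedding pipeline is region-permutation equivariant", {
  msn <- random_msn(30, seed = 11)
  perm <- sample(30)
  g <- diffusion_embed(normalized_angle_affinity(sparsify_rows(msn)), k = 3)
  gp <- diffusion_embed(normalized_angle_affinity(
    sparsify_rows(msn[perm, perm])), k = 3)
  for (j in 1:3) {
    cosang <- abs(sum(gp$scores[, j] * g$scores[perm, j])) /
      (sqrt(sum(gp$scores[, j]^2)) * sqrt(sum(g$scores[perm, j]^2)))
    expect_gt(cosang, 1 - 1e-8)
  }
})
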