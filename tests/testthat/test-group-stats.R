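make_design <- function(n_per_group = 25, n_sites = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(subject_id = sprintf("s%03d", 1:n),
             group = rep(c("AD", "NC"), each = n_per_group),
             age = rnorm(n, 73, 6), sex = rbinom(n, 1, 0.5),
             education = rnorm(n, 16, 2),
             site = factor(rep_len(seq_len(n_sites), n)))
}

test_that("single-site harmonization is a pass-through", {
  d <- make_design(10, n_sites = 1)
  vals <- matrix(rnorm(20 * 8), 20)
  expect_equal(combat_harmonize(vals, d), vals)
})

test_that("ComBat removes a planted additive site offset", {
  set.seed(2)
  d <- make_design(50, n_sites = 2)
  delta <- 1.5
  vals <- matrix(rnorm(100 * 40), 100)
  vals[d$site == 2, ] <- vals[d$site == 2, ] + delta
  harm <- combat_harmonize(vals, d)
  site_diff <- colMeans(harm[d$site == 2, ]) - colMeans(harm[d$site == 1, ])
  expect_lt(abs(mean(site_diff)), 0.05 * delta)
})

test_that("ComBat preserves a group effect orthogonal to site", {
  set.seed(3)
  d <- make_design(50, n_sites = 2)
  eff <- rnorm(40, 0, 0.8)
  vals <- matrix(rnorm(100 * 40), 100)
  vals[d$group == "AD", ] <- sweep(vals[d$group == "AD", ], 2, eff, "+")
  vals[d$site == 2, ] <- vals[d$site == 2, ] + 1
  before <- colMeans(vals[d$group == "AD", ]) - colMeans(vals[d$group == "NC", ])
  harm <- combat_harmonize(vals, d)
  after <- colMeans(harm[d$group == "AD", ]) - colMeans(harm[d$group == "NC", ])
  expect_lt(mean(abs(after - before)) / mean(abs(before)), 0.05)
  # a site with one subject is rejected
  d2 <- d; d2$site <- factor(c(1, rep(2, 99)))
  expect_error(combat_harmonize(vals, d2), "single subject")
})

test_that("covariate-free GLM contrast equals the classical two-sample t", {
  set.seed(4)
  d <- make_design(20, n_sites = 1)
  vals <- matrix(rnorm(40 * 15), 40)
  sm <- glm_contrast(vals, d, covariates = character(0))
  is_ad <- d$group == "AD"
  for (r in 1:15) {
    expect_equal(sm$t[r], oracle_two_sample_t(vals[is_ad, r], vals[!is_ad, r]),
                 tolerance = 1e-10)
  }
  expect_equal(sm$q, oracle_bh(sm$p), tolerance = 1e-12)
})

test_that("identical group samples give zero t", {
  d <- make_design(10, n_sites = 1)
  half <- matrix(rnorm(10 * 6), 10)
  vals <- rbind(half, half)     # AD rows literally equal NC rows
  sm <- glm_contrast(vals, d, covariates = character(0))
  expect_true(all(abs(sm$t) < 1e-10))
})

test_that("GLM contrast is invariant to affine covariate rescaling and flags collinearity", {
  set.seed(5)
  d <- make_design(25, n_sites = 1)
  vals <- matrix(rnorm(50 * 10), 50)
  t1 <- glm_contrast(vals, d)$t
  d2 <- d; d2$age <- 10 * d$age - 300; d2$education <- d$education / 4
  expect_equal(glm_contrast(vals, d2)$t, t1, tolerance = 1e-9)
  d3 <- d; d3$education <- 2 * d3$age + 1
  expect_error(glm_contrast(vals, d3), "education")
})

test_that("GLM recovers planted effect signs through covariate noise", {
  set.seed(6)
  n_regions <- 120
  eff <- rnorm(n_regions, 0, 0.8)
  d <- make_design(100, n_sites = 1)
  vals <- matrix(rnorm(200 * n_regions), 200) + 0.05 * d$age + 0.1 * d$sex
  vals[d$group == "AD", ] <- sweep(vals[d$group == "AD", ], 2, eff, "+")
  sm <- glm_contrast(vals, d)
  big <- abs(eff) >= 0.8
  expect_gte(mean(sign(sm$t[big]) == sign(eff[big])), 0.95)
  expect_gt(cor(sm$t, eff), 0.9)
})

test_that("label aggregation averages member regions", {
  set.seed(7)
  vals <- matrix(rnorm(8 * 21), 8)
  atlas <- generate_atlas(21)
  agg <- aggregate_by_label(vals, atlas, "class")
  labs <- atlas$econo_class
  for (l in levels(labs)) {
    expect_equal(unname(agg[, l]),
                 unname(rowMeans(vals[, labs == l, drop = FALSE])),
                 tolerance = 1e-12)
  }
  # one region per label: identity up to ordering
  atlas1 <- data.frame(region_id = paste0("r", 1:7),
                       econo_class = factor(levels(labs), levels = levels(labs)))
  vals1 <- matrix(rnorm(3 * 7), 3)
  expect_equal(unname(aggregate_by_label(vals1, atlas1, "class")),
               unname(vals1))
  # single-label collapse: the global mean
  atlas_one <- data.frame(region_id = paste0("r", 1:21),
                          econo_class = rep("asso1", 21),
                          stringsAsFactors = FALSE)
  expect_equal(unname(aggregate_by_label(vals, atlas_one, "class")[, 1]),
               unname(rowMeans(vals)))
  # a vocabulary level with no member regions is rejected
  atlas_empty <- data.frame(region_id = paste0("r", 1:21),
                            econo_class = factor(rep("asso1", 21),
                                                 levels = levels(labs)))
  expect_error(aggregate_by_label(vals, atlas_empty, "class"), "empty label")
})

test_that("KS statistic matches the ECDF sweep oracle and is symmetric", {
  set.seed(8)
  a <- rnorm(70); b <- rnorm(90, 0.4)
  res <- ks_compare(a, b)
  expect_equal(res$D, oracle_ks_D(a, b), tolerance = 1e-12)
  expect_equal(res$D, ks_compare(b, a)$D)
  expect_true(res$D >= 0 && res$D <= 1)
  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(runif(20), runif(20) + 5)$D, 1)
  expect_error(ks_compare(numeric(0), a), "non-empty")
})

test_that("BH step-up q-values match the hand-computed oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.5, 6)), rep(0.5, 6))
  set.seed(9)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pooled class-level KS table covers global plus every class", {
  ch <- small_cohort(n_regions = 42, n_per_group = c(AD = 8, NC = 8), seed = 10)
  vals <- t(vapply(ch$features, function(f) f[, 1], numeric(42)))
  atlas <- generate_atlas(42)
  tab <- ks_by_class(vals, ch$metadata$group, atlas, "class")
  expect_setequal(tab$label, c("global", levels(atlas$econo_class)))
  expect_true(all(tab$D >= 0 & tab$D <= 1))
  tab2 <- ks_by_class(vals, ch$metadata$group, atlas, "class", pool = FALSE)
  expect_equal(nrow(tab2), nrow(tab))
})
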