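#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on an
#' intercept plus the covariates, with the two-sided p from the t transform
#' at `n - n_covariates - 2` degrees of freedom. With no covariates this is
#' the plain Pearson correlation. Used to relate class-level gradient means
#' to cognitive scores while adjusting age, sex, and education.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x c) or NULL.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  stop_if(length(x) != length(y), "`x` and `y` must be the same length")
  stop_if(anyNA(x) || anyNA(y), "inputs contain NA")
  n <- length(x)
  ncov <- 0L
  if (!is.null(covariates) && length(covariates) > 0) {
    covariates <- as.matrix(covariates)
    stop_if(nrow(covariates) != n, "covariate rows must match `x`")
    ncov <- ncol(covariates)
    z <- cbind(1, covariates)
    stop_if(qr(z)$rank < ncol(z), "rank-deficient covariates")
    x <- lm.fit(z, x)$residuals
    y <- lm.fit(z, y)$residuals
  }
  stop_if(n <= ncov + 2, "need n > n_covariates + 2 observations")
  r <- cor(x, y)
  df <- n - ncov - 2
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tval), df, lower.tail = FALSE), df = df)
}

#' Default SVR hyperparameter grid
#'
#' Linear-kernel grid over the regularization cost `C` (log-spaced 0.01 to
#' 100) and the epsilon-insensitive tube width.
#'
#' @return data.frame with columns `cost` and `epsilon`.
#' @export
svr_default_grid <- function() {
  expand.grid(cost = 10^seq(-2, 2, by = 1),
              epsilon = c(0.01, 0.1, 1))
}

make_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

fit_svr <- function(x, y, cost, epsilon, kernel) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = kernel,
             cost = cost, epsilon = epsilon, scale = FALSE)
}

# Standardize train columns; apply the train moments to test. Constant
# columns are left centered only (no division by zero).
scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' Nested cross-validated SVR prediction of a cognitive score
#'
#' Outer k-fold cross-validation with inner-fold hyperparameter tuning:
#' within each outer training set, features are standardized (the same
#' moments are applied to the held-out fold), an inner CV selects the grid
#' point with minimal mean squared error, the tuned model is refit on the
#' whole outer training set, and the held-out fold is predicted. Performance
#' is the Pearson correlation between observed and out-of-fold predicted
#' scores, concatenated across folds. No information crosses from test to
#' train: scaling and tuning see training data only.
#'
#' @param features subject x p numeric matrix (e.g. regional gradient-1
#'   scores or regional MSN strength).
#' @param target numeric score vector.
#' @param n_outer outer folds (default 5).
#' @param n_inner inner folds (default 5).
#' @param grid hyperparameter data.frame (`cost`, `epsilon`); a single row
#'   skips inner tuning.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param seed RNG seed controlling the fold assignment.
#' @return list of class `svr_prediction`: `r`, `predicted`, `observed`,
#'   `folds`, `tuned` (per-outer-fold chosen hyperparameters), `seed`.
#' @export
svr_predict_cv <- function(features, target, n_outer = 5, n_inner = 5,
                           grid = svr_default_grid(), kernel = "linear",
                           seed = 1L) {
  features <- as.matrix(features)
  check_matrix(features, "features")
  stop_if(length(target) != nrow(features),
          "`target` must have one value per subject")
  stop_if(anyNA(target), "`target` contains NA")
  stop_if(sd(target) == 0, "constant target: correlation undefined")
  n <- nrow(features)
  stop_if(n < 5 * n_outer, sprintf("need >= %d subjects for %d outer folds",
                                   5 * n_outer, n_outer))
  folds <- make_folds(n, n_outer, seed)
  predicted <- numeric(n)
  tuned <- vector("list", n_outer)
  for (fo in seq_len(n_outer)) {
    tr <- folds != fo
    sc <- scale_train_test(features[tr, , drop = FALSE],
                           features[!tr, , drop = FALSE])
    y_tr <- target[tr]
    if (nrow(grid) > 1) {
      inner_folds <- make_folds(sum(tr), n_inner, derive_seed(seed, fo))
      mse <- vapply(seq_len(nrow(grid)), function(gi) {
        errs <- vapply(seq_len(n_inner), function(fi) {
          itr <- inner_folds != fi
          isc <- scale_train_test(sc$train[itr, , drop = FALSE],
                                  sc$train[!itr, , drop = FALSE])
          fit <- fit_svr(isc$train, y_tr[itr], grid$cost[gi],
                         grid$epsilon[gi], kernel)
          mean((predict(fit, isc$test) - y_tr[!itr])^2)
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(mse)
    } else {
      best <- 1L
    }
    tuned[[fo]] <- grid[best, , drop = FALSE]
    fit <- fit_svr(sc$train, y_tr, grid$cost[best], grid$epsilon[best], kernel)
    predicted[!tr] <- predict(fit, sc$test)
  }
  structure(list(r = cor(target, predicted), predicted = predicted,
                 observed = target, folds = folds,
                 tuned = do.call(rbind, tuned), seed = seed),
            class = "svr_prediction")
}

#' Permutation significance of an SVR prediction
#'
#' Re-runs the full nested-CV pipeline on permuted targets and reports
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. The whole pipeline —
#' scaling, tuning, fitting — is repeated per permutation so the null
#' distribution reflects every source of optimism.
#'
#' @param observed an `svr_prediction` from [svr_predict_cv()].
#' @param features,target the inputs that produced it.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param ... further arguments passed on to [svr_predict_cv()] (grid,
#'   kernel, fold counts); fold assignment reuses the observed run's seed.
#' @return list: `p`, `r_obs`, `r_perm` (vector).
#' @export
permutation_p <- function(observed, features, target, n_perm = 1000,
                          seed = 1L, ...) {
  stop_if(!inherits(observed, "svr_prediction"),
          "`observed` must come from svr_predict_cv()")
  stop_if(!is_count(n_perm), "`n_perm` must be a positive integer")
  r_perm <- vapply(seq_len(n_perm), function(b) {
    y_perm <- with_seed(derive_seed(seed, b), sample(target))
    svr_predict_cv(features, y_perm, seed = observed$seed, ...)$r
  }, numeric(1))
  list(p = (1 + sum(r_perm >= observed$r)) / (1 + n_perm),
       r_obs = observed$r, r_perm = r_perm)
}

#' Compare two feature sets for predicting the same scores
#'
#' Runs the identical nested-CV SVR (same subjects, same fold assignments,
#' same grid) on two feature sets — e.g. regional gradient-1 scores versus
#' regional MSN strength — for each supplied target, optionally with
#' permutation p-values.
#'
#' @param gradient_features,strength_features subject x p matrices over the
#'   same subjects.
#' @param targets named list (or data.frame) of score vectors.
#' @param n_perm permutations per score (0 skips significance).
#' @param seed RNG seed (folds shared across feature sets).
#' @param ... passed to [svr_predict_cv()].
#' @return data.frame: score, feature_set, r, p, n.
#' @export
compare_feature_sets <- function(gradient_features, strength_features,
                                 targets, n_perm = 0, seed = 1L, ...) {
  gradient_features <- as.matrix(gradient_features)
  strength_features <- as.matrix(strength_features)
  stop_if(nrow(gradient_features) != nrow(strength_features),
          "feature sets must cover the same subjects")
  if (is.data.frame(targets)) targets <- as.list(targets)
  rows <- list()
  for (score in names(targets)) {
    y <- targets[[score]]
    for (set_name in c("gradient", "strength")) {
      feats <- if (set_name == "gradient") gradient_features else strength_features
      fit <- svr_predict_cv(feats, y, seed = seed, ...)
      p <- NA_real_
      if (n_perm > 0) {
        p <- permutation_p(fit, feats, y, n_perm = n_perm,
                           seed = derive_seed(seed, match(score, names(targets))),
                           ...)$p
      }
      rows[[length(rows) + 1L]] <-
        data.frame(score = score, feature_set = set_name, r = fit$r, p = p,
                   n = length(y), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
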