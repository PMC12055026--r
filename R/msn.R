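#' Standardize morphometric features across regions
#'
#' Each of the five feature columns is z-scored across brain regions (sample
#' SD, ddof = 1), the conventional preprocessing before correlating
#' multi-feature regional profiles: it puts thickness (mm), volume (mm^3),
#' area (mm^2) and the curvatures (1/mm^2, 1/mm) on a common unitless scale so
#' no feature dominates the profile correlation.
#'
#' @param table regions x features numeric matrix; >= 3 regions, no missing
#'   values, every feature with nonzero variance.
#' @return matrix of the same shape with column means 0 and sample SDs 1.
#' @export
zscore_features <- function(table) {
  check_matrix(table, "table")
  stop_if(nrow(table) < 3, "need at least 3 regions to standardize")
  sds <- apply(table, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(table)[sds == 0] %||% which(sds == 0)
    stop(sprintf("zero-variance feature(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  scale(table)[, , drop = FALSE]
}

#' Compute a subject's morphometric similarity network
#'
#' Entry (i, j) is the Pearson correlation between region i's and region j's
#' standardized 5-feature profiles. The diagonal is set to 0: self-similarity
#' is uninformative and would always survive row sparsification. A region
#' whose profile is constant (correlation undefined) gets zero entries with a
#' warning; this cannot arise from the synthetic generator and is defensive
#' only.
#'
#' @param table standardized regions x features matrix (see
#'   [zscore_features()]).
#' @return symmetric regions x regions matrix with zero diagonal.
#' @export
compute_msn <- function(table) {
  check_matrix(table, "table")
  stop_if(nrow(table) < 3, "need at least 3 regions")
  stop_if(ncol(table) < 2, "need at least 2 features per region")
  row_sd <- apply(table, 1, sd)
  constant <- row_sd == 0
  msn <- suppressWarnings(cor(t(table)))
  if (any(constant)) {
    warning(sprintf("%d region(s) with constant feature profile; correlations set to 0",
                    sum(constant)), call. = FALSE)
    msn[constant, ] <- 0
    msn[, constant] <- 0
  }
  diag(msn) <- 0
  # cor() is symmetric up to representation; enforce exactly
  msn <- (msn + t(msn)) / 2
  dimnames(msn) <- list(rownames(table), rownames(table))
  msn
}

#' Regional MSN strength
#'
#' The sum of each region's correlation coefficients with all other regions
#' (off-diagonal row sums), the regional summary used as the comparator
#' feature set in cognition prediction.
#'
#' @param msn symmetric MSN matrix (diagonal ignored).
#' @return named numeric vector, one strength per region.
#' @export
regional_strength <- function(msn) {
  check_square_symmetric(msn, "msn")
  rowSums(msn) - diag(msn)
}
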