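# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stage seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000003 + offset) %% 2147483647L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_matrix <- function(x, name) {
  stop_if(!is.matrix(x) || !is.numeric(x), sprintf("`%s` must be a numeric matrix", name))
  stop_if(anyNA(x), sprintf("`%s` contains missing values", name))
  invisible(x)
}

check_square_symmetric <- function(x, name, tol = 1e-8) {
  check_matrix(x, name)
  stop_if(nrow(x) != ncol(x), sprintf("`%s` must be square", name))
  stop_if(max(abs(x - t(x))) > tol, sprintf("`%s` must be symmetric", name))
  invisible(x)
}

# Names of the five morphometric features, fixed by the MSN definition.
MSN_FEATURES <- c("thickness", "volume", "area", "gauss_curv", "mean_curv")

# Seven-level vocabularies for the two cortical partitions.
VON_ECONOMO_CLASSES <- c("prim_sens", "sec_sens", "asso1", "asso2",
                         "limbic", "prim_motor", "insula")
YEO_NETWORKS <- c("VIS", "SOM", "DAN", "SAL", "LIM", "FPN", "DMN")
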