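#' @useDynLib strokefeat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats bw.nrd0 cor cov density dist ecdf kmeans median plogis
#'   pnorm predict quantile rbeta rbinom rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

# Run code under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-subject seed derived from a cohort seed; stays well
# below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, index) {
  ((as.numeric(seed) %% 2^20) * 1597 + as.numeric(index) * 7919) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
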