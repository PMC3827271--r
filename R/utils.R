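#' @useDynLib kabcoal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp rlnorm sd median quantile rpois runif
#' @importFrom utils head tail combn
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL means "use the
# current stream" (and advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stream of child seeds from one master seed, keeping every value
# a valid 32-bit integer. Used so that loci / replicates are individually
# reproducible from a single user-facing seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
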