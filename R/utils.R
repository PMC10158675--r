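#' @importFrom stats rnorm runif rbinom rexp predict quantile sd var median
#'   plogis qlogis binomial glm.fit setNames aggregate
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

.datatable.aware <- TRUE

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package funnel
# through this so that a seed argument fully determines the result.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a stream-specific child seed from a parent seed; keeps every derived
# seed inside 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647L)
}

# last-observation-carried-forward; leading NAs left in place
locf <- function(x) {
  idx <- cumsum(!is.na(x))
  out <- rep(NA_real_, length(x))
  out[idx > 0] <- x[!is.na(x)][idx[idx > 0]]
  out
}

# backward fill (next-observation-carried-backward)
nocb <- function(x) rev(locf(rev(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
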