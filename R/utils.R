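#' @keywords internal
"_PACKAGE"

#' @useDynLib n2vko, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm rbinom glm binomial coef sd var predict
#' @importFrom utils head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a single integer seed pins down every result.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from one global seed
#'
#' A single pipeline seed is expanded deterministically into independent
#' seeds for each stochastic stage (walk simulation, skip-gram training,
#' fold assignment, oversampling) so that stages do not share RNG streams.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"walks"` or `"folds"`.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h + 1
  as.integer(s %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
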