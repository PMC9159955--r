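#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic package operations do
#' not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Stable string hash (FNV-style, folded below 2^31) so that adding pipeline
#' stages never perturbs the seeds of existing ones.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(stage)) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Robust quantile shorthand used throughout the package
#' @noRd
rquant <- function(x, p) as.numeric(quantile(x, p, names = FALSE, type = 7))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
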