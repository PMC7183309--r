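#' Evaluate code with a private RNG stream
#'
#' Runs `code` after `set.seed(seed)`, restoring the caller's
#' `.Random.seed` afterwards, so every generator in this package is a
#' pure function of its parameters and seed and leaves the global RNG
#' untouched.
#'
#' @param seed single finite integer-like number
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-normalize gene symbols
#'
#' Symbols are uppercased and trimmed before any join, because gene
#' symbols in mouse datasets are inconsistently cased across sources.
#'
#' @param x character vector of gene symbols
#' @return uppercased, trimmed character vector
#' @export
norm_symbols <- function(x) toupper(trimws(as.character(x)))

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x) || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# row variances with ddof = 1, no apply() overhead
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
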