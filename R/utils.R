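# Internal plumbing: seeded evaluation and per-subject RNG streams.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' clobber the caller's RNG state. With `seed = NULL` the expression runs
#' under the ambient RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Stable 31-bit hash of a string
#'
#' Polynomial rolling hash over UTF-8 bytes, kept below 2^31 so it can be
#' combined with a master seed and passed to [set.seed()]. Used to derive
#' independent per-subject RNG streams from `(master seed, subject_id)`.
#'
#' @param s character scalar.
#' @return non-negative integer < 2^31.
#' @keywords internal
str_hash31 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% m
  as.integer(h)
}

#' Derive a child seed from a master seed and a label
#' @keywords internal
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + str_hash31(label)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
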