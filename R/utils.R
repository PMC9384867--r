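# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`,
#' and restores the previous state on exit.  With `seed = NULL` the
#' expression runs against the current RNG stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible sub-seed
#'
#' Stable 31-bit string hash of (master seed, stage labels), giving
#' every pipeline stage and species its own independent, reproducible
#' RNG stream.
#'
#' @param master master seed (integer).
#' @param ... further labels (stage name, species, ...).
#' @return an integer seed in 1..2^31-1.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
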