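# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Generators must be pure functions of (parameters, seed): the global RNG
#' stream is saved, seeded, and restored so callers see no side effects.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("'seed' must be a single integer")
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

geometric_mean <- function(x) exp(mean(log(x)))

# Numeric scalar check with a named error.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("'%s' must be a single positive number", name)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be in [0, 1]", name)
  invisible(x)
}

#' Normalize chromosome names
#'
#' Chromosome matching everywhere in the package is exact string equality:
#' "1" and "chr1" are different sequences. This helper lets a caller (or the
#' command-line wrapper) normalize names on ingest when two inputs use
#' different conventions.
#'
#' @param x character vector of chromosome names.
#' @param style "none" (leave untouched), "strip" (remove a leading "chr"),
#'   or "add" (prefix "chr" where missing).
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_chroms(c("chr1", "2"), "add")
normalize_chroms <- function(x, style = c("none", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
    none  = x,
    strip = sub("^chr", "", x),
    add   = ifelse(grepl("^chr", x), x, paste0("chr", x))
  )
}
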