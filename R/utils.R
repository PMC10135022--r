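# Internal helpers shared across the package.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG, evaluates `expr`, and restores the previous RNG state so
#' that seeded operations inside the package never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# round-half-up to `digits` decimals; base round() rounds half to even,
# which disagrees with the coverage/sites reporting convention used here
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# shared BLOSUM62 accessor (lazy, cached)
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}
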