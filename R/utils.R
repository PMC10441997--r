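#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so seeded helpers never perturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a global seed and a stage counter
#'
#' Counter-based fan-out: each pipeline stage draws its own seed from the
#' global one, so adding a stage never shifts another stage's random stream.
#' Uses a MINSTD-style multiplicative step; results stay in (0, 2^31 - 1).
#'
#' @param seed Global integer seed.
#' @param index Non-negative stage counter.
#' @return An integer seed usable with [set.seed()].
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index) * 10007 + 1) %% m
  as.integer(s + (s == 0))
}

# format numbers for TSV writers: 10 significant digits, UTF-8
fmt_num <- function(x) formatC(x, digits = 10, format = "g")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))
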