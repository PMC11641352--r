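# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Transcribed tables often carry the Unicode minus (U+2212); normalise to
# ASCII hyphen-minus so numeric parsing works.
#' @noRd
normalize_minus <- function(x) gsub("−", "-", x)

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# FNV-1a 32-bit hash, computed in double arithmetic (exact below 2^53).
# Used to map topological path strings onto hashed-fingerprint bit positions.
#' @noRd
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# XOR of two non-negative doubles < 2^32 without integer overflow.
#' @noRd
bitwXor64 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  hi * 2147483648 + as.numeric(lo)
}
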