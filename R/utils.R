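#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# FNV-1a 32-bit over the UTF-8 bytes of a string; arithmetic kept in double
# (exact below 2^53) with explicit mod 2^32. Used for taxonomy fingerprints.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# xor of two nonnegative doubles < 2^32 without 32-bit integer overflow
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

# local RNG scope: runs expr under set.seed(seed) and restores the prior state
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_littriage <- function(msg, class) {
  stop(structure(
    class = c(class, "littriage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
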