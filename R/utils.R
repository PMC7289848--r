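#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive a child RNG seed from a parent seed and an index so that streams are
# hierarchical: adding cells/frames never perturbs earlier draws.
# 32-bit helpers on doubles (exact below 2^53): xor, multiply mod 2^32.
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}

mulmod32 <- function(a, b) {
  ((a %% 65536) * b %% 4294967296 +
     ((a %/% 65536) * b %% 65536) * 65536) %% 4294967296
}

# MurmurHash3 32-bit finalizer: full avalanche, so that nearby (seed, index)
# pairs yield decorrelated child seeds.
hash32 <- function(x) {
  x <- xor32(x, x %/% 65536)
  x <- mulmod32(x, 2246822507)
  x <- xor32(x, x %/% 8192)
  x <- mulmod32(x, 3266489909)
  xor32(x, x %/% 65536)
}

child_seed <- function(seed, index) {
  h <- hash32((as.numeric(seed) %% 4294967296 +
                 mulmod32(as.numeric(index) %% 4294967296, 2654435761)) %%
                4294967296)
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
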