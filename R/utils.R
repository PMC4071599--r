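# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, min = -Inf, max = Inf,
                               strict_min = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0L)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite values", name),
         call. = FALSE)
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad || any(x > max)) {
    stop(sprintf("`%s` must lie in %s%g, %g]", name,
                 if (strict_min) "(" else "[", min, max), call. = FALSE)
  }
  invisible(x)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp output files with a config fingerprint without pulling in a
# digest dependency. Arithmetic is done in double precision; all intermediate
# values stay below 2^53 so the result is exact.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for doubles holding 32-bit unsigned values (bitwXor needs < 2^31)
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

# Deterministic child seed derivation: keeps results reproducible when one
# user-supplied seed must drive several independent simulation stages.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
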