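stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("'%s' = %g is outside %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}

assert_numeric_vec <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stopf("'%s' must be a numeric vector of length >= %d", name, min_len)
  }
  if (!all(is.finite(x))) stopf("'%s' contains non-finite values", name)
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over a character scalar; used for config hashes in manifests.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double to avoid
    # 32-bit integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by 16777619 = 2^24 + 403, exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic per-trial seed derivation (counter scheme, kept < 2^31).
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(counter)) %% 2147483647)
}
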