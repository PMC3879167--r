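#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic 31-bit substream seed from a master seed plus a string key.
# FNV-1a over the key, folded with the master seed; keeps everything inside
# .Machine$integer.max so set.seed() never sees doubles.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483629 + 1)
}

# FNV-1a-style hex digest of a string (folded to 31 bits); used for
# measurement provenance.
fnv1a_hex <- function(x) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(x)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
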