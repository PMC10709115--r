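# Internal helpers shared across modules.

# Stable 32-bit FNV-1a hash of a string, reduced below 2^31 so it is always a
# valid R integer seed. Used to derive per-gene seeds from gene ids so that
# study results are independent of gene order and of which genes are present.
stable_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit multiply by the FNV prime 16777619, done in doubles mod 2^31
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' Derive a reproducible child seed from a master seed and an identifier
#'
#' Combines a master seed with a stable hash of `id` (e.g. a gene id), so
#' per-gene randomness is reproducible and independent of processing order.
#'
#' @param master_seed Integer master seed.
#' @param id Character identifier.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, id) {
  as.integer((as.double(master_seed) * 48271 + stable_hash(id)) %% .Machine$integer.max)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
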