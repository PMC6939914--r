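#' @keywords internal
"_PACKAGE"

# Derive a substream seed from a master seed.  Every stochastic function in
# the package draws from its own stream so that adding draws to one component
# never perturbs another.  Streams are spaced by a large odd multiplier and
# folded back into the valid 32-bit range.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + 1000003 * stream) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("recolonize_param_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("recolonize_degenerate_error", "error")))
}

# FNV-1a hash of a serialized R object; used for config fingerprints in run
# manifests (no external digest dependency).
fnv1a_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
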