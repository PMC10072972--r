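#' @include AllGenerics.R
NULL

# FNV-1a hash of a raw vector as 8 hex digits; 32-bit arithmetic carried in
# doubles (split at 16 bits so products stay exact)
.fnv1a <- function(raw) {
  h <- 2166136261
  for (b in as.integer(raw)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint an R object
#'
#' Stable 8-hex-digit FNV-1a hash of the serialized object; used to stamp
#' every pipeline artifact with the configuration that produced it.
#'
#' @param x any R object.
#' @return 8-character hex string.
#' @export
configHash <- function(x) {
  .fnv1a(serialize(x, NULL, version = 2))
}
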