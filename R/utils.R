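#' @useDynLib apvtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd var quantile rnorm pwilcox p.adjust qlogis
#' @importFrom utils combn read.delim write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_apv <- function(kind, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(kind, "apv_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' FNV-1a content hash of a character representation
#'
#' Small deterministic 32-bit hash used to fingerprint feature catalogues in
#' serialized models, so a model can refuse rows produced under a different
#' catalogue.
#'
#' @param x object; deparsed to character before hashing.
#' @return hex string of the 32-bit FNV-1a hash.
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keep everything in
    # doubles because h exceeds R's 32-bit signed integer range
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # exact 32-bit modular multiply via 16-bit limbs (products stay < 2^53)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a per-subject seed from a cohort seed; stays below 2^31.
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}
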