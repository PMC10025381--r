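# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit hash of a character label, used to derive independent
# RNG seeds for (replication, environment) sampling streams.  Plain polynomial
# rolling hash; collisions are harmless (streams only need to be reproducible
# and label-keyed, not cryptographically distinct).
label_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Combine a base seed with an offset, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Centre a vector and rescale so its *population* variance equals `target`.
# Used by the phenotype simulator so realized variance components match the
# configured ones by construction.  Degenerate inputs (length < 2 or constant)
# are returned as zeros.
scale_to_var <- function(x, target) {
  n <- length(x)
  if (target <= 0 || n < 2L) return(rep(0, n))
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v == 0) return(rep(0, n))
  x * sqrt(target / v)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
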