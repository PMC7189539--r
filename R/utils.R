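# Seeding and hashing helpers. All randomness in the package flows through
# with_seed()/derive_seed() so that datasets are reproducible piecewise from
# one master seed without clobbering the caller's RNG state.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so package internals never
#' perturb user RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Derive a stable sub-seed from a master seed and a key
#'
#' FNV-1a hash over the UTF-8 bytes of the key components, folded with the
#' master seed and reduced below 2^31 so it is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param ... Components (coerced to character) identifying the substream.
#' @return A non-negative integer < 2^31.
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\x1f")
  h <- fnv1a32(charToRaw(enc2utf8(key)))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a over a raw vector, in double arithmetic (exact below 2^53).
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # a < 2^32, b < 2^8: split a to stay within bitwXor's integer range
  lo <- a %% 2^16
  hi <- a %/% 2^16
  hi * 2^16 + bitwXor(as.integer(lo), as.integer(b))
}

#' Content hash of an R object
#'
#' Order-sensitive polynomial checksum over the object's serialization,
#' vectorised so large objects hash quickly. Used for provenance stamps, not
#' cryptography.
#'
#' @param x Any serialisable object.
#' @return Hex string.
#' @keywords internal
object_hash <- function(x) {
  b <- as.double(serialize(x, NULL, version = 2))
  p <- 2147483629
  w <- (seq_along(b) %% 97 + 1) * (seq_along(b) %% 89 + 3)
  h1 <- sum(b * w) %% p
  h2 <- sum((b + 7) * rev(w)) %% p
  sprintf("%08x%08x", h1 %% 4294967296, h2 %% 4294967296)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
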