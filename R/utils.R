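# Internal helpers: seeded evaluation, seed derivation, id hashing.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed; kept below 2^31 - 1 so it is a valid R integer.
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (b in utf8ToInt(paste0("s", salt))) {
    s <- (s * 69069 + b) %% 2147483629
  }
  as.integer(s %% 2147483647)
}

# FNV-1a 32-bit over a character vector; identifies frozen id sets.
hash_ids <- function(ids) {
  bytes <- utf8ToInt(paste(ids, collapse = "\x1f"))
  h <- 2166136261
  # h held as a double in [0, 2^32); xor on the low 16 bits only (the byte
  # fits there), multiply by the FNV prime in 16-bit halves to stay exact.
  for (b in bytes) {
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h0 <- bitwXor(as.integer(h0), as.integer(b))
    h <- h1 * 65536 + h0
    lo <- (h %% 65536) * 16777619
    hi <- (((h - (h %% 65536)) / 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# Proportional stratified allocation with largest-remainder rounding; returns
# integer quota per stratum. Ties on the fractional part break by stratum
# order, which keeps the allocation deterministic.
largest_remainder <- function(sizes, fraction) {
  quota <- sizes * fraction
  base <- floor(quota)
  total <- round(sum(quota))
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  pmin(as.integer(base), as.integer(sizes))
}
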