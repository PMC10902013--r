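# Internal helpers shared across modules.

# Pa * um^2 = 1e-6 uN; applied wherever a modulus meets a geometry prefactor.
.UN_PER_PA_UM2 <- 1e-6

.stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                          finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    .stop_invalid("`", name, "` must be a single non-missing number")
  }
  if (finite && !is.finite(x)) .stop_invalid("`", name, "` must be finite")
  if (positive && x <= 0) .stop_invalid("`", name, "` must be > 0")
  if (nonneg && x < 0) .stop_invalid("`", name, "` must be >= 0")
  invisible(x)
}

.check_numeric <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    .stop_invalid("`", name, "` must be a non-empty finite numeric vector")
  }
  if (nonneg && any(x < 0)) .stop_invalid("`", name, "` must be non-negative")
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  .check_scalar(seed, "seed")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# FNV-1a hash of an R object (via serialization), returned as 8 hex digits.
# Used only to stamp result tables with a configuration fingerprint.
.fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 0x811c9dc5
  for (b in bytes) {
    # XOR only touches the low byte (b < 256); keeps h a double-safe 32-bit int
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
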