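# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a base seed and integer tags.
# Keeps results in [1, 2^31 - 2] so they are valid set.seed() inputs.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483563
  for (k in tags) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483563
  as.integer(s + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Snap intensities to the 8-bit grid used by PNG interchange, so that
# in-memory images and save/load round-trips are bit-identical.
quantize8 <- function(x) round(x * 255) / 255

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of an R object via its canonical JSON serialization.
object_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
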