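# Internal helpers shared across modules.

# Snap doubles to the nearest float32-representable value by a round trip
# through 4-byte IEEE storage. Needed because R has no native float type
# but maps and stored volume levels are float32 on disk.
asFloat32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
                 "numeric", n = length(x), size = 4L, endian = "little")
  dim(out) <- d
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run an expression with a private RNG stream seeded from `seed`, restoring
# the caller's RNG state afterwards, so fixtures are bit-reproducible
# without clobbering user randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sanitized entry keys: the store's directory names.
sanitizeKey <- function(x) {
  y <- tolower(x)
  y <- gsub("[^a-z0-9_-]", "_", y)
  if (!nzchar(y)) stopf("empty key after sanitization: '%s'", x)
  y
}

# Smallest unsigned integer mode holding `maxLabel`.
latticeModeFor <- function(maxLabel) {
  if (maxLabel <= 255L) "uint8"
  else if (maxLabel <= 65535L) "uint16"
  else "uint32"
}

# Named label histogram of an integer array (names = label values).
labelHistogram <- function(labels) {
  tab <- table(as.vector(labels))
  stats::setNames(as.integer(tab), names(tab))
}
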