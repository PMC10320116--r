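# Minimal MessagePack serializer/deserializer.
#
# Covers the subset the BinaryCIF container model needs: nil, booleans,
# integers (up to 32-bit magnitude), float64, strings, binary blobs,
# arrays and string-keyed maps. R mapping: named list <-> map, unnamed
# list <-> array, raw <-> bin, character(1) <-> str, integerish
# numeric(1) <-> int, other numeric(1) <-> float64, NULL <-> nil.
# Scalars must be wrapped in lists to express arrays of length 1.

.mpU32 <- function(x) {
  # big-endian unsigned 32-bit of a non-negative double
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}
.mpU16 <- function(x) as.raw(c(x %/% 256, x %% 256))

.mpEncodeInt <- function(v) {
  if (v >= 0) {
    if (v < 128) as.raw(v)
    else if (v < 256) c(as.raw(0xcc), as.raw(v))
    else if (v < 65536) c(as.raw(0xcd), .mpU16(v))
    else c(as.raw(0xce), .mpU32(v))
  } else {
    if (v >= -32) as.raw(256 + v)                       # negative fixint
    else if (v >= -128) c(as.raw(0xd0), as.raw(256 + v))
    else if (v >= -32768) c(as.raw(0xd1), .mpU16(65536 + v))
    else c(as.raw(0xd2), .mpU32(4294967296 + v))
  }
}

.mpEncodeLen <- function(n, fixTag, fixMax, tag16, tag32) {
  if (n < fixMax) as.raw(fixTag + n)
  else if (n < 65536) c(as.raw(tag16), .mpU16(n))
  else c(as.raw(tag32), .mpU32(n))
}

.mpEncodeOne <- function(x) {
  if (is.null(x)) return(list(as.raw(0xc0)))
  if (is.raw(x)) {
    n <- length(x)
    head <- if (n < 256) c(as.raw(0xc4), as.raw(n))
            else if (n < 65536) c(as.raw(0xc5), .mpU16(n))
            else c(as.raw(0xc6), .mpU32(n))
    return(list(head, x))
  }
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms) && all(nzchar(nms))) {
      parts <- list(.mpEncodeLen(length(x), 0x80, 16, 0xde, 0xdf))
      for (i in seq_along(x)) {
        parts <- c(parts, .mpEncodeOne(nms[i]), .mpEncodeOne(x[[i]]))
      }
      return(parts)
    }
    parts <- list(.mpEncodeLen(length(x), 0x90, 16, 0xdc, 0xdd))
    for (el in x) parts <- c(parts, .mpEncodeOne(el))
    return(parts)
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    b <- charToRaw(enc2utf8(x))
    n <- length(b)
    head <- if (n < 32) as.raw(0xa0 + n)
            else if (n < 256) c(as.raw(0xd9), as.raw(n))
            else if (n < 65536) c(as.raw(0xda), .mpU16(n))
            else c(as.raw(0xdb), .mpU32(n))
    return(list(head, b))
  }
  if (is.logical(x)) {
    stopifnot(length(x) == 1L)
    return(list(as.raw(if (isTRUE(x)) 0xc3 else 0xc2)))
  }
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    if (is.finite(x) && x == round(x) && abs(x) < 2^31)
      return(list(.mpEncodeInt(as.numeric(x))))
    return(list(c(as.raw(0xcb),
                  rev(writeBin(as.numeric(x), raw(), size = 8L,
                               endian = "little")))))
  }
  stopf("msgpack: cannot encode object of class %s", class(x)[1])
}

#' Encode an R object as MessagePack bytes
#'
#' @param x NULL, logical/numeric/character scalar, raw vector, unnamed
#'   list (array) or fully named list (map), nested arbitrarily.
#' @return raw vector.
#' @keywords internal
#' @export
msgpackEncode <- function(x) {
  do.call(c, .mpEncodeOne(x))
}

.mpDecodeOne <- function(bytes, pos) {
  if (pos > length(bytes)) stopf("invalid bcif: truncated msgpack stream")
  b <- as.integer(bytes[pos]); pos <- pos + 1L
  take <- function(n) {
    if (n == 0) return(raw(0))
    if (pos + n - 1L > length(bytes)) stopf("invalid bcif: truncated msgpack stream")
    r <- bytes[pos:(pos + n - 1L)]
    pos <<- pos + n
    r
  }
  u <- function(r) sum(as.numeric(r) * 256^((length(r) - 1):0))
  readArr <- function(n) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      d <- .mpDecodeOne(bytes, pos); out[[i]] <- d$value; pos <<- d$pos
    }
    list(value = out, pos = pos)
  }
  readMap <- function(n) {
    out <- vector("list", n); nms <- character(n)
    for (i in seq_len(n)) {
      k <- .mpDecodeOne(bytes, pos); pos <<- k$pos
      v <- .mpDecodeOne(bytes, pos); pos <<- v$pos
      nms[i] <- as.character(k$value)
      out[i] <- list(v$value)
    }
    names(out) <- nms
    list(value = out, pos = pos)
  }
  if (b < 0x80) return(list(value = as.numeric(b), pos = pos))
  if (b >= 0xe0) return(list(value = as.numeric(b - 256L), pos = pos))
  if (b >= 0x80 && b <= 0x8f) return(readMap(b - 0x80))
  if (b >= 0x90 && b <= 0x9f) return(readArr(b - 0x90))
  if (b >= 0xa0 && b <= 0xbf) {
    n <- b - 0xa0
    return(list(value = rawToChar(take(n)), pos = pos))
  }
  switch(sprintf("%02x", b),
    "c0" = list(value = NULL, pos = pos),
    "c2" = list(value = FALSE, pos = pos),
    "c3" = list(value = TRUE, pos = pos),
    "c4" = { n <- u(take(1)); list(value = take(n), pos = pos) },
    "c5" = { n <- u(take(2)); list(value = take(n), pos = pos) },
    "c6" = { n <- u(take(4)); list(value = take(n), pos = pos) },
    "ca" = list(value = readBin(rev(take(4)), "numeric", size = 4L,
                                endian = "little"), pos = pos),
    "cb" = list(value = readBin(rev(take(8)), "numeric", size = 8L,
                                endian = "little"), pos = pos),
    "cc" = list(value = u(take(1)), pos = pos),
    "cd" = list(value = u(take(2)), pos = pos),
    "ce" = list(value = u(take(4)), pos = pos),
    "d0" = { v <- u(take(1)); list(value = if (v >= 128) v - 256 else v, pos = pos) },
    "d1" = { v <- u(take(2)); list(value = if (v >= 32768) v - 65536 else v, pos = pos) },
    "d2" = { v <- u(take(4)); list(value = if (v >= 2^31) v - 2^32 else v, pos = pos) },
    "d9" = { n <- u(take(1)); list(value = rawToChar(take(n)), pos = pos) },
    "da" = { n <- u(take(2)); list(value = rawToChar(take(n)), pos = pos) },
    "db" = { n <- u(take(4)); list(value = rawToChar(take(n)), pos = pos) },
    "dc" = { n <- u(take(2)); readArr(n) },
    "dd" = { n <- u(take(4)); readArr(n) },
    "de" = { n <- u(take(2)); readMap(n) },
    "df" = { n <- u(take(4)); readMap(n) },
    stopf("invalid bcif: unsupported msgpack tag 0x%02x", b)
  )
}

#' Decode MessagePack bytes to an R object
#'
#' Inverse of [msgpackEncode()] on the supported subset; maps become
#' named lists, arrays unnamed lists.
#'
#' @param bytes raw vector.
#' @return the decoded object.
#' @keywords internal
#' @export
msgpackDecode <- function(bytes) {
  if (!is.raw(bytes)) stopf("invalid bcif: expected raw bytes")
  d <- .mpDecodeOne(bytes, 1L)
  if (d$pos != length(bytes) + 1L)
    stopf("invalid bcif: %d trailing bytes", length(bytes) + 1L - d$pos)
  d$value
}
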