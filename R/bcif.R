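# BinaryCIF codec: composable columnar encodings (delta, run-length,
# integer packing, fixed point, interval quantization, string dictionary)
# over a MessagePack container. Integer chains are lossless; the two
# float steps carry explicit error bounds. 32-bit magnitude is enforced
# throughout: refusal rather than silent wraparound.

.INT32_MAX <- 2147483647

.checkInt32 <- function(v, what) {
  if (length(v) && max(abs(v)) > .INT32_MAX)
    stopf("%s: values exceed 32-bit range", what)
}

# ---- primitive encodings ------------------------------------------------

#' Delta-encode an integer array
#'
#' The first output element is 0 and each further element is the
#' difference to its predecessor; the first source value is returned
#' separately as the origin. Decoding is a prefix sum plus the origin.
#'
#' @param values integer-valued numeric vector (32-bit representable).
#' @return list with `deltas` and `origin`.
#' @export
encodeDelta <- function(values) {
  values <- as.numeric(values)
  .checkInt32(values, "delta encoding")
  if (!length(values)) return(list(deltas = numeric(0), origin = 0))
  list(deltas = c(0, diff(values)), origin = values[1])
}

#' @rdname encodeDelta
#' @param deltas,origin output of `encodeDelta`.
#' @export
decodeDelta <- function(deltas, origin) {
  if (!length(deltas)) return(numeric(0))
  origin + cumsum(c(0, deltas[-1]))
}

#' Run-length encode an integer array
#'
#' Collapses runs of equal consecutive values to flattened
#' (value, count) pairs.
#'
#' @param values integer-valued numeric vector.
#' @return list with `pairs` (flattened value,count sequence) and
#'   `srcSize` (original length).
#' @export
encodeRLE <- function(values) {
  values <- as.numeric(values)
  .checkInt32(values, "run-length encoding")
  if (!length(values)) return(list(pairs = numeric(0), srcSize = 0))
  r <- rle(values)
  list(pairs = as.numeric(rbind(r$values, r$lengths)), srcSize = length(values))
}

#' @rdname encodeRLE
#' @param pairs,srcSize output of `encodeRLE`.
#' @export
decodeRLE <- function(pairs, srcSize) {
  if (!length(pairs)) return(numeric(0))
  idx <- seq(1, length(pairs), by = 2)
  out <- rep(pairs[idx], times = pairs[idx + 1])
  if (length(out) != srcSize) stopf("invalid bcif: run-length size mismatch")
  out
}

.packBounds <- function(byteCount, unsigned) {
  if (!byteCount %in% c(1L, 2L)) stopf("invalid packing: byteCount must be 1 or 2")
  if (unsigned) c(lower = 0, upper = if (byteCount == 1L) 255 else 65535)
  else if (byteCount == 1L) c(lower = -128, upper = 127)
  else c(lower = -32768, upper = 32767)
}

#' Pack 32-bit integers into 1- or 2-byte elements
#'
#' Each value v is emitted as floor(|v| / B) copies of the relevant bound
#' B (the upper bound for v >= 0, the lower bound for v < 0) followed by
#' the remainder; decoding accumulates while elements equal a bound.
#'
#' @param values integer-valued numeric vector (32-bit representable);
#'   must be non-negative when `unsigned`.
#' @param byteCount 1 or 2.
#' @param unsigned logical.
#' @return numeric vector of packed elements, each within the target
#'   byte range.
#' @export
packIntegers <- function(values, byteCount = 1L, unsigned = FALSE) {
  values <- as.numeric(values)
  .checkInt32(values, "integer packing")
  b <- .packBounds(as.integer(byteCount), unsigned)
  if (unsigned && length(values) && any(values < 0))
    stopf("invalid packing: negative values with unsigned packing")
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    bound <- if (v >= 0) b["upper"] else b["lower"]
    k <- abs(v) %/% abs(bound)
    out[[i]] <- c(rep(bound, k), v - k * bound)
  }
  unlist(out, use.names = FALSE) %||% numeric(0)
}

#' @rdname packIntegers
#' @param packed output of `packIntegers`.
#' @export
unpackIntegers <- function(packed, byteCount = 1L, unsigned = FALSE) {
  b <- .packBounds(as.integer(byteCount), unsigned)
  out <- numeric(0)
  acc <- 0
  for (p in packed) {
    acc <- acc + p
    if (!(p == b["upper"] || (!unsigned && p == b["lower"]))) {
      out <- c(out, acc)
      acc <- 0
    }
  }
  if (acc != 0) stopf("invalid bcif: unterminated integer packing")
  out
}

#' Fixed-point encode a float array
#'
#' Multiplies by `factor` and rounds; decoding divides, so the maximum
#' absolute reconstruction error is 0.5 / factor.
#'
#' @param values numeric vector.
#' @param factor positive scale.
#' @return integer-valued numeric vector.
#' @export
encodeFixedPoint <- function(values, factor) {
  if (factor <= 0) stopf("invalid fixed point: factor must be positive")
  out <- round(as.numeric(values) * factor)
  if (length(out) && max(abs(out)) > .INT32_MAX)
    stopf("fixed-point overflow: scaled values exceed 32-bit range")
  out
}

#' @rdname encodeFixedPoint
#' @param encoded output of `encodeFixedPoint`.
#' @export
decodeFixedPoint <- function(encoded, factor) as.numeric(encoded) / factor

#' Interval-quantize a float array
#'
#' Clamps to [lo, hi] and maps linearly onto `steps` integer codes
#' 0..steps-1; decoding inverts the linear map, so the maximum absolute
#' error for in-range values is (hi - lo) / (2 (steps - 1)).
#'
#' @param values numeric vector.
#' @param lo,hi interval bounds, lo < hi.
#' @param steps integer >= 2.
#' @return numeric vector of codes in 0..steps-1.
#' @export
encodeIntervalQuantization <- function(values, lo, hi, steps) {
  if (steps < 2) stopf("invalid quantization: steps must be >= 2")
  if (!(lo < hi)) stopf("invalid quantization: lo must be < hi")
  v <- pmin(pmax(as.numeric(values), lo), hi)
  round((v - lo) / (hi - lo) * (steps - 1))
}

#' @rdname encodeIntervalQuantization
#' @param encoded codes from `encodeIntervalQuantization`.
#' @export
decodeIntervalQuantization <- function(encoded, lo, hi, steps) {
  lo + as.numeric(encoded) / (steps - 1) * (hi - lo)
}

#' Dictionary-encode a string array
#'
#' Unique strings are concatenated into one dictionary with an offset
#' table; each row stores an index into the dictionary, -1 for absent
#' (NA) values.
#'
#' @param values character vector (NA allowed).
#' @return list with `stringData`, `offsets` (0-based, length U+1) and
#'   `indices` (0-based, -1 = absent).
#' @export
encodeStringArray <- function(values) {
  uniq <- unique(values[!is.na(values)])
  indices <- match(values, uniq) - 1L
  indices[is.na(indices)] <- -1L
  lens <- nchar(uniq, type = "bytes")
  list(stringData = paste(uniq, collapse = ""),
       offsets = c(0, cumsum(lens)),
       indices = as.numeric(indices))
}

#' @rdname encodeStringArray
#' @param stringData,offsets,indices output of `encodeStringArray`.
#' @export
decodeStringArray <- function(stringData, offsets, indices) {
  n <- length(offsets) - 1L
  uniq <- if (n > 0)
    substring(stringData, offsets[seq_len(n)] + 1, offsets[seq_len(n) + 1L])
  else character(0)
  out <- rep(NA_character_, length(indices))
  present <- indices >= 0
  out[present] <- uniq[indices[present] + 1]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- byte-level terminal encoding --------------------------------------
# BinaryCIF ByteArray type codes.
.BA <- c(int8 = 1, int16 = 2, int32 = 3, uint8 = 4, uint16 = 5, uint32 = 6,
         float32 = 32, float64 = 33)

.byteArrayEncode <- function(values, type) {
  switch(as.character(type),
    "1" = writeBin(as.integer(values), raw(), size = 1L, endian = "little"),
    "2" = writeBin(as.integer(values), raw(), size = 2L, endian = "little"),
    "3" = writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
    "4" = writeBin(as.integer(values), raw(), size = 1L, endian = "little"),
    "5" = writeBin(as.integer(values), raw(), size = 2L, endian = "little"),
    "6" = writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
    "32" = writeBin(as.numeric(values), raw(), size = 4L, endian = "little"),
    "33" = writeBin(as.numeric(values), raw(), size = 8L, endian = "little"),
    stopf("invalid bcif: unknown byte-array type %s", type))
}

.byteArrayDecode <- function(bytes, type) {
  switch(as.character(type),
    "1" = readBin(bytes, "integer", n = length(bytes), size = 1L,
                  signed = TRUE, endian = "little"),
    "2" = readBin(bytes, "integer", n = length(bytes) / 2, size = 2L,
                  signed = TRUE, endian = "little"),
    "3" = readBin(bytes, "integer", n = length(bytes) / 4, size = 4L,
                  endian = "little"),
    "4" = readBin(bytes, "integer", n = length(bytes), size = 1L,
                  signed = FALSE, endian = "little"),
    "5" = readBin(bytes, "integer", n = length(bytes) / 2, size = 2L,
                  signed = FALSE, endian = "little"),
    "6" = {
      lo <- readBin(bytes, "integer", n = length(bytes) / 4, size = 4L,
                    endian = "little")
      ifelse(lo < 0, lo + 2^32, lo)
    },
    "32" = readBin(bytes, "numeric", n = length(bytes) / 4, size = 4L,
                   endian = "little"),
    "33" = readBin(bytes, "numeric", n = length(bytes) / 8, size = 8L,
                   endian = "little"),
    stopf("invalid bcif: unknown byte-array type %s", type))
}

# Pick the cheapest terminal representation of a packed/plain int array:
# 1-byte packing, 2-byte packing, or plain int32.
.bestPacking <- function(values) {
  unsignedOk <- !length(values) || min(values) >= 0
  best <- list(bytes = 4 * length(values), byteCount = 0L, unsigned = FALSE)
  for (bc in c(1L, 2L)) for (us in unique(c(unsignedOk, FALSE))) {
    b <- .packBounds(bc, us)
    bound <- ifelse(values >= 0, b["upper"], abs(b["lower"]))
    n <- sum(abs(values) %/% bound + 1)
    if (n * bc < best$bytes) best <- list(bytes = n * bc, byteCount = bc, unsigned = us)
  }
  best
}

# Apply Delta -> IntegerPacking (or plain int32) to an integer array,
# returning data bytes plus the encoding chain, appended to `chain`.
.encodeIntTail <- function(values, chain) {
  d <- encodeDelta(values)
  chain <- c(chain, list(list(kind = "Delta", origin = d$origin,
                              srcType = .BA[["int32"]])))
  pk <- .bestPacking(d$deltas)
  if (pk$byteCount == 0L) {
    chain <- c(chain, list(list(kind = "ByteArray", type = .BA[["int32"]])))
    list(data = .byteArrayEncode(d$deltas, .BA[["int32"]]), encoding = chain)
  } else {
    packed <- packIntegers(d$deltas, pk$byteCount, pk$unsigned)
    type <- if (pk$unsigned) {
      if (pk$byteCount == 1L) .BA[["uint8"]] else .BA[["uint16"]]
    } else {
      if (pk$byteCount == 1L) .BA[["int8"]] else .BA[["int16"]]
    }
    chain <- c(chain, list(list(kind = "IntegerPacking",
                                byteCount = pk$byteCount,
                                isUnsigned = pk$unsigned,
                                srcSize = length(d$deltas)),
                           list(kind = "ByteArray", type = type)))
    list(data = .byteArrayEncode(packed, type), encoding = chain)
  }
}

#' Build an encoded BinaryCIF column
#'
#' Default chains: plain integer columns use delta + integer packing;
#' label rasters prepend run-length encoding; float columns use either
#' interval quantization (255 steps over the data range, the volume
#' default) or fixed-point, followed by the integer chain; string columns
#' use the dictionary encoding. Every integer chain is lossless.
#'
#' @param name column name.
#' @param values the column values.
#' @param type one of "int", "labels", "float-quant", "float-fixed",
#'   "float64", "string".
#' @param lo,hi,steps interval quantization parameters ("float-quant").
#' @param factor fixed-point scale ("float-fixed").
#' @return list modeling an encoded column: `name`, `data` (list with
#'   raw `data` and `encoding` chain), `mask`.
#' @export
bcifColumn <- function(name, values,
                       type = c("int", "labels", "float-quant",
                                "float-fixed", "float64", "string"),
                       lo = NULL, hi = NULL, steps = 255L, factor = 1000) {
  type <- match.arg(type)
  enc <- switch(type,
    "int" = .encodeIntTail(values, list()),
    "labels" = {
      r <- encodeRLE(values)
      .encodeIntTail(r$pairs,
                     list(list(kind = "RunLength", srcType = .BA[["int32"]],
                               srcSize = r$srcSize)))
    },
    "float-quant" = {
      if (is.null(lo)) lo <- min(values)
      if (is.null(hi)) hi <- max(values)
      if (hi <= lo) hi <- lo + 1   # degenerate constant column
      q <- encodeIntervalQuantization(values, lo, hi, steps)
      .encodeIntTail(q, list(list(kind = "IntervalQuantization",
                                  min = lo, max = hi, numSteps = steps,
                                  srcType = .BA[["float32"]])))
    },
    "float-fixed" = {
      fp <- encodeFixedPoint(values, factor)
      .encodeIntTail(fp, list(list(kind = "FixedPoint", factor = factor,
                                   srcType = .BA[["float64"]])))
    },
    "float64" = list(
      data = .byteArrayEncode(values, .BA[["float64"]]),
      encoding = list(list(kind = "ByteArray", type = .BA[["float64"]]))),
    "string" = {
      sa <- encodeStringArray(values)
      idx <- .encodeIntTail(sa$indices, list())
      off <- .encodeIntTail(sa$offsets, list())
      list(data = idx$data,
           encoding = list(list(kind = "StringArray",
                                dataEncoding = idx$encoding,
                                stringData = sa$stringData,
                                offsetEncoding = off$encoding,
                                offsets = off$data)))
    })
  list(name = name, data = list(data = enc$data, encoding = enc$encoding),
       mask = NULL)
}

#' Decode one BinaryCIF column
#'
#' Applies the column's encoding chain in reverse, reproducing integer
#' and string columns exactly and float columns within the documented
#' quantization bound.
#'
#' @param column a column model as produced by [bcifColumn()] or read
#'   back by [bcifDeserialize()].
#' @return the decoded values (numeric or character).
#' @export
bcifDecodeColumn <- function(column) {
  .applyDecode(column$data$data, column$data$encoding)
}

.applyDecode <- function(data, encodings) {
  current <- data
  for (e in rev(encodings)) {
    current <- switch(e$kind,
      "ByteArray" = .byteArrayDecode(current, e$type),
      "IntegerPacking" = {
        v <- unpackIntegers(current, as.integer(e$byteCount),
                            isTRUE(e$isUnsigned))
        if (length(v) != e$srcSize) stopf("invalid bcif: packing size mismatch")
        v
      },
      "Delta" = decodeDelta(current, e$origin),
      "RunLength" = decodeRLE(current, e$srcSize),
      "FixedPoint" = decodeFixedPoint(current, e$factor),
      "IntervalQuantization" =
        decodeIntervalQuantization(current, e$min, e$max, e$numSteps),
      "StringArray" = {
        idx <- .applyDecode(current, e$dataEncoding)
        off <- .applyDecode(e$offsets, e$offsetEncoding)
        decodeStringArray(e$stringData, off, idx)
      },
      stopf("invalid bcif: unknown encoding kind '%s'", e$kind))
  }
  current
}

# ---- container ----------------------------------------------------------

.BCIF_VERSION <- "0.3.0"
.BCIF_ENCODER <- "volseg 0.1.0"

#' Assemble a BinaryCIF category
#'
#' @param name category name (e.g. "_volume_data").
#' @param columns list of columns from [bcifColumn()].
#' @param rowCount logical row count shared by all columns.
#' @return category model list.
#' @export
bcifCategory <- function(name, columns, rowCount) {
  list(name = name, rowCount = rowCount, columns = columns)
}

#' Assemble a BinaryCIF data block
#'
#' @param header block header string.
#' @param categories list from [bcifCategory()].
#' @return data block model list.
#' @export
bcifBlock <- function(header, categories) {
  list(header = header, categories = categories)
}

#' Serialize data blocks to BinaryCIF bytes
#'
#' Lays the blocks out in the BinaryCIF container model (a versioned map
#' with an encoder tag and the data blocks) and serializes it with
#' MessagePack. [bcifDeserialize()] is its inverse on the logical model.
#'
#' @param blocks list of blocks from [bcifBlock()].
#' @return raw vector.
#' @export
bcifSerialize <- function(blocks) {
  msgpackEncode(list(encoder = .BCIF_ENCODER, version = .BCIF_VERSION,
                     dataBlocks = unname(blocks)))
}

#' @rdname bcifSerialize
#' @param bytes raw vector from `bcifSerialize`.
#' @export
bcifDeserialize <- function(bytes) {
  obj <- tryCatch(msgpackDecode(bytes), error = function(e) {
    if (grepl("invalid bcif", conditionMessage(e))) stop(e)
    stopf("invalid bcif: %s", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$version))
    stopf("invalid bcif: missing container version")
  major <- strsplit(as.character(obj$version), ".", fixed = TRUE)[[1]][1:2]
  supported <- strsplit(.BCIF_VERSION, ".", fixed = TRUE)[[1]][1:2]
  if (!identical(major, supported))
    stopf("unsupported version: %s", obj$version)
  obj$dataBlocks
}
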