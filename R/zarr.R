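# Minimal chunked, compressed N-dimensional array storage following the
# Zarr v2 on-disk convention: a `.zarray` JSON document describing shape,
# chunks, dtype and compressor, next to one zlib-compressed file per
# chunk named "i.j.k". Arrays are stored in "F" order (first axis
# fastest), matching R's memory layout, so chunk payloads are straight
# writeBin dumps of sub-arrays. Box reads touch only intersecting chunks.

.zarrDtypes <- list(
  "<f4" = list(what = "numeric", size = 4L, signed = TRUE),
  "|u1" = list(what = "integer", size = 1L, signed = FALSE),
  "<u2" = list(what = "integer", size = 2L, signed = FALSE),
  "<u4" = list(what = "integer", size = 4L, signed = TRUE)  # labels < 2^31
)

.zarrDtypeFor <- function(mode) {
  switch(mode, float32 = "<f4", uint8 = "|u1", uint16 = "<u2", uint32 = "<u4",
         stopf("unsupported dtype mode: %s", mode))
}

zarrWriteArray <- function(data, dir, mode, chunk = c(64L, 64L, 64L)) {
  dims <- dim(data)
  stopifnot(length(dims) == 3L)
  dtype <- .zarrDtypeFor(mode)
  dt <- .zarrDtypes[[dtype]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    zarr_format = 2L,
    shape = as.integer(dims),
    chunks = as.integer(pmin(chunk, dims)),
    dtype = dtype,
    compressor = list(id = "zlib", level = 6L),
    fill_value = 0L,
    order = "F",
    filters = NULL
  )
  jsonlite::write_json(meta, file.path(dir, ".zarray"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  ch <- meta$chunks
  nchunks <- ceiling(dims / ch)
  for (cx in seq_len(nchunks[1])) for (cy in seq_len(nchunks[2]))
    for (cz in seq_len(nchunks[3])) {
      xs <- ((cx - 1L) * ch[1] + 1L):min(cx * ch[1], dims[1])
      ys <- ((cy - 1L) * ch[2] + 1L):min(cy * ch[2], dims[2])
      zs <- ((cz - 1L) * ch[3] + 1L):min(cz * ch[3], dims[3])
      block <- data[xs, ys, zs, drop = FALSE]
      bytes <- if (dt$what == "numeric")
        writeBin(as.numeric(block), raw(), size = dt$size, endian = "little")
      else
        writeBin(as.integer(block), raw(), size = dt$size, endian = "little")
      writeBin(memCompress(bytes, "gzip"),
               file.path(dir, sprintf("%d.%d.%d", cx - 1L, cy - 1L, cz - 1L)))
    }
  invisible(dir)
}

zarrMeta <- function(dir) {
  p <- file.path(dir, ".zarray")
  if (!file.exists(p)) stopf("corrupt entry: missing %s", p)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

# Read the half-open voxel box [lo, hi) (0-based) from a stored array,
# touching only the chunks the box intersects.
zarrReadBox <- function(dir, lo, hi) {
  meta <- zarrMeta(dir)
  dims <- as.integer(meta$shape)
  ch <- as.integer(meta$chunks)
  dt <- .zarrDtypes[[meta$dtype]]
  if (is.null(dt)) stopf("corrupt entry: unknown dtype %s", meta$dtype)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo < 0L) || any(hi > dims) || any(lo >= hi))
    stopf("empty region: box [%s, %s) outside dims %s",
          paste(lo, collapse = ","), paste(hi, collapse = ","),
          paste(dims, collapse = ","))
  odims <- hi - lo
  out <- array(if (dt$what == "numeric") 0 else 0L, dim = odims)
  c0 <- lo %/% ch
  c1 <- (hi - 1L) %/% ch
  for (cx in c0[1]:c1[1]) for (cy in c0[2]:c1[2]) for (cz in c0[3]:c1[3]) {
    cpath <- file.path(dir, sprintf("%d.%d.%d", cx, cy, cz))
    if (!file.exists(cpath)) stopf("corrupt entry: missing chunk %s", cpath)
    cdimsFull <- pmin((c(cx, cy, cz) + 1L) * ch, dims) - c(cx, cy, cz) * ch
    bytes <- memDecompress(readBin(cpath, "raw", file.info(cpath)$size), "gzip")
    vals <- readBin(bytes, dt$what, n = prod(cdimsFull), size = dt$size,
                    signed = dt$signed, endian = "little")
    block <- array(vals, dim = cdimsFull)
    # overlap of this chunk with the requested box, in global coords
    glo <- pmax(lo, c(cx, cy, cz) * ch)
    ghi <- pmin(hi, c(cx, cy, cz) * ch + cdimsFull)
    bl <- glo - c(cx, cy, cz) * ch   # 0-based within chunk
    ol <- glo - lo                   # 0-based within output
    out[(ol[1] + 1L):(ol[1] + ghi[1] - glo[1]),
        (ol[2] + 1L):(ol[2] + ghi[2] - glo[2]),
        (ol[3] + 1L):(ol[3] + ghi[3] - glo[3])] <-
      block[(bl[1] + 1L):(bl[1] + ghi[1] - glo[1]),
            (bl[2] + 1L):(bl[2] + ghi[2] - glo[2]),
            (bl[3] + 1L):(bl[3] + ghi[3] - glo[3])]
  }
  out
}

zarrReadArray <- function(dir) {
  meta <- zarrMeta(dir)
  zarrReadBox(dir, c(0L, 0L, 0L), as.integer(meta$shape))
}
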