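# Size-budgeted queries over stored entries: metadata echo, downsampling
# level selection, chunk-local box reads, and BinaryCIF packing of the
# results.

#' Construct a BoxQuery
#'
#' @param source,entryId entry keys.
#' @param channel "volume" or "lattice".
#' @param lo,hi half-open box `[lo, hi)` in 0-based factor-1 voxel
#'   coordinates.
#' @param maxPoints positive point budget (values per response).
#' @param latticeId lattice id for the lattice channel.
#' @return a \linkS4class{BoxQuery}
#' @export
BoxQuery <- function(source, entryId, channel = "volume",
                     lo = c(0L, 0L, 0L), hi, maxPoints = 1e6,
                     latticeId = NA_integer_) {
  maxPoints <- suppressWarnings(as.numeric(maxPoints))
  if (length(maxPoints) != 1L || !is.finite(maxPoints) || maxPoints <= 0)
    stopf("invalid budget: maxPoints must be a positive number")
  new("BoxQuery", source = source, entryId = entryId, channel = channel,
      latticeId = as.integer(latticeId), lo = as.integer(lo),
      hi = as.integer(hi), maxPoints = as.numeric(maxPoints))
}

#' Metadata and annotations of a stored entry
#'
#' Returns the verbatim content of the entry's metadata.json and
#' annotations.json documents, as parsed lists.
#'
#' @param source,entryId entry keys.
#' @param root database root.
#' @return list with `metadata` and `annotations`.
#' @export
getMetadata <- function(source, entryId, root) {
  dir <- .checkEntryExists(root, source, entryId)
  list(metadata = .readMeta(dir), annotations = .readAnnotations(dir))
}

#' Choose the downsampling level for a box under a point budget
#'
#' Returns the smallest factor f with
#' `prod(ceiling(boxDims / f)) <= maxPoints`. When even the coarsest
#' level overruns the budget, the largest factor is returned with
#' `budgetExceeded = TRUE`.
#'
#' @param boxDims integer(3) box dimensions in factor-1 voxels.
#' @param factors available factors, sorted ascending.
#' @param maxPoints positive budget.
#' @return list with `factor` and `budgetExceeded`.
#' @export
chooseLevel <- function(boxDims, factors, maxPoints) {
  if (length(maxPoints) != 1L || !is.finite(maxPoints) || maxPoints <= 0)
    stopf("invalid budget: maxPoints must be positive")
  if (!length(factors)) stopf("invalid budget: no factors available")
  for (f in factors) {
    if (prod(ceiling(boxDims / f)) <= maxPoints)
      return(list(factor = as.integer(f), budgetExceeded = FALSE))
  }
  list(factor = as.integer(max(factors)), budgetExceeded = TRUE)
}

#' Answer a box query from the store
#'
#' Clamps the requested box to the grid, picks the downsampling level
#' with [chooseLevel()], maps the box to level space as
#' `[floor(lo/f), ceiling(hi/f))` (the returned region always covers the
#' request), and reads only the chunks the level-space box intersects. A
#' full-grid query at factor 1 returns the original data exactly.
#'
#' @param q a \linkS4class{BoxQuery}.
#' @param root database root.
#' @return a \linkS4class{SliceResult}
#' @export
queryBox <- function(q, root) {
  validObject(q)
  dir <- .checkEntryExists(root, q@source, q@entryId)
  meta <- .readMeta(dir)
  dims <- as.integer(unlist(meta$dims))
  factors <- as.integer(unlist(meta$factors))
  lo <- pmax(q@lo, 0L)
  hi <- pmin(q@hi, dims)
  if (any(lo >= hi)) stopf("empty region: box is empty after clamping")
  sel <- chooseLevel(hi - lo, factors, q@maxPoints)
  f <- sel$factor
  adir <- if (q@channel == "volume") {
    file.path(dir, "volume", f)
  } else {
    if (is.na(q@latticeId) ||
        !q@latticeId %in% as.integer(unlist(meta$lattice_ids)))
      stopf("not found: lattice %s in %s/%s", q@latticeId, q@source, q@entryId)
    file.path(dir, "segmentation", q@latticeId, f)
  }
  levelDimsAll <- as.integer(unlist(meta$level_dims[[as.character(f)]]))
  llo <- lo %/% f
  lhi <- pmin(-((-hi) %/% f), levelDimsAll)   # ceiling division, clamped
  values <- zarrReadBox(adir, llo, lhi)
  stats <- if (q@channel == "volume")
    unlist(meta$volume_stats[[as.character(f)]])
  else
    unlist(meta$lattice_histograms[[as.character(q@latticeId)]][[as.character(f)]])
  new("SliceResult", factor = f, levelLo = as.integer(llo),
      levelHi = as.integer(lhi), values = values, stats = stats,
      budgetExceeded = sel$budgetExceeded, channel = q@channel,
      latticeId = q@latticeId)
}

#' Fetch all meshes of an entry
#'
#' @param source,entryId entry keys.
#' @param root database root.
#' @return list with `meshes` (list of \linkS4class{Mesh}) and
#'   `segments` (the mesh-kind segment annotation records).
#' @export
queryMeshes <- function(source, entryId, root) {
  dir <- .checkEntryExists(root, source, entryId)
  meta <- .readMeta(dir)
  if (!length(meta$mesh_info))
    stopf("not found: entry %s/%s has no meshes", source, entryId)
  ann <- .readAnnotations(dir)
  meshSegs <- Filter(function(s) identical(s$kind, "mesh"), ann$segments)
  list(meshes = .loadMeshes(dir, meta), segments = meshSegs)
}

# ---- BinaryCIF response assembly ---------------------------------------

.QUANT_STEPS <- 255L

.volumeInfoCategory <- function(meta, r) {
  f <- as.character(r@factor)
  stats <- unlist(meta$volume_stats[[f]])
  cols <- list(
    bcifColumn("source", meta$source, "string"),
    bcifColumn("entry_id", meta$entry_id, "string"),
    bcifColumn("channel", r@channel, "string"),
    bcifColumn("factor", r@factor, "int"),
    bcifColumn("level_lo_x", r@levelLo[1], "int"),
    bcifColumn("level_lo_y", r@levelLo[2], "int"),
    bcifColumn("level_lo_z", r@levelLo[3], "int"),
    bcifColumn("level_dim_x", dim(r@values)[1], "int"),
    bcifColumn("level_dim_y", dim(r@values)[2], "int"),
    bcifColumn("level_dim_z", dim(r@values)[3], "int"),
    bcifColumn("orig_dim_x", as.integer(unlist(meta$dims))[1], "int"),
    bcifColumn("orig_dim_y", as.integer(unlist(meta$dims))[2], "int"),
    bcifColumn("orig_dim_z", as.integer(unlist(meta$dims))[3], "int"),
    bcifColumn("voxel_size_x", unlist(meta$voxel_size)[1], "float64"),
    bcifColumn("voxel_size_y", unlist(meta$voxel_size)[2], "float64"),
    bcifColumn("voxel_size_z", unlist(meta$voxel_size)[3], "float64"),
    bcifColumn("min", unname(stats["min"]), "float64"),
    bcifColumn("max", unname(stats["max"]), "float64"),
    bcifColumn("mean", unname(stats["mean"]), "float64"),
    bcifColumn("sigma", unname(stats["sigma"]), "float64"),
    bcifColumn("budget_exceeded", as.numeric(r@budgetExceeded), "int")
  )
  bcifCategory("_volume_info", cols, 1L)
}

#' Pack a query result as a BinaryCIF payload
#'
#' Builds one data block. Volume results carry a `_volume_info` category
#' (entry keys, chosen factor, level-space box, original dims, voxel
#' size, per-level stats) and a `_volume_data` category whose single
#' `values` column is interval-quantized (255 steps over the level's
#' value range), delta-encoded and integer-packed. Lattice results carry
#' `_segmentation_data` (lossless run-length chain) plus a
#' `_segment_table` with the annotation records of the lattice's
#' segments. Mesh payloads carry `_mesh_vertex` / `_mesh_triangle`
#' categories. Decoding with [decodeResponse()] reproduces label values
#' exactly and volume values within (max - min) / 508 for the default
#' 255-step quantization.
#'
#' @param result a \linkS4class{SliceResult} from [queryBox()], or the
#'   mesh payload from [queryMeshes()].
#' @param metadata the entry metadata list (from [getMetadata()]).
#' @param annotations the entry annotations list.
#' @return raw BinaryCIF bytes.
#' @export
buildResponse <- function(result, metadata, annotations = NULL) {
  if (is(result, "SliceResult")) {
    info <- .volumeInfoCategory(metadata, result)
    v <- as.numeric(result@values)
    if (result@channel == "volume") {
      st <- unlist(metadata$volume_stats[[as.character(result@factor)]])
      lo <- unname(st["min"]); hi <- unname(st["max"])
      dataCat <- bcifCategory("_volume_data", list(
        bcifColumn("values", v, "float-quant", lo = lo, hi = hi,
                   steps = .QUANT_STEPS)), length(v))
      return(bcifSerialize(list(bcifBlock("volume", list(info, dataCat)))))
    }
    dataCat <- bcifCategory("_segmentation_data", list(
      bcifColumn("values", v, "labels")), length(v))
    segs <- Filter(function(s) identical(s$kind, "lattice") &&
                     s$lattice_id == result@latticeId,
                   annotations$segments %||% list())
    segCat <- bcifCategory("_segment_table", list(
      bcifColumn("segment_id", vapply(segs, function(s) as.numeric(s$segment_id),
                                      numeric(1)), "int"),
      bcifColumn("label_value", vapply(segs, function(s) as.numeric(s$label_value),
                                       numeric(1)), "int"),
      bcifColumn("lattice_id", vapply(segs, function(s) as.numeric(s$lattice_id),
                                      numeric(1)), "int"),
      bcifColumn("name", vapply(segs, function(s) as.character(s$name),
                                character(1)), "string"),
      bcifColumn("colour_r", vapply(segs, function(s) unlist(s$colour)[1],
                                    numeric(1)), "float-fixed", factor = 10000),
      bcifColumn("colour_g", vapply(segs, function(s) unlist(s$colour)[2],
                                    numeric(1)), "float-fixed", factor = 10000),
      bcifColumn("colour_b", vapply(segs, function(s) unlist(s$colour)[3],
                                    numeric(1)), "float-fixed", factor = 10000),
      bcifColumn("colour_a", vapply(segs, function(s) unlist(s$colour)[4],
                                    numeric(1)), "float-fixed", factor = 10000)
    ), length(segs))
    return(bcifSerialize(list(bcifBlock("segmentation",
                                        list(info, dataCat, segCat)))))
  }
  # mesh payload
  cats <- list()
  for (m in result$meshes) {
    v <- m@vertices; tr <- m@triangles
    cats <- c(cats, list(
      bcifCategory(sprintf("_mesh_vertex_%d", m@meshId), list(
        bcifColumn("x", v[, 1], "float-fixed", factor = 1000),
        bcifColumn("y", v[, 2], "float-fixed", factor = 1000),
        bcifColumn("z", v[, 3], "float-fixed", factor = 1000)), nrow(v)),
      bcifCategory(sprintf("_mesh_triangle_%d", m@meshId), list(
        bcifColumn("v1", tr[, 1], "int"),
        bcifColumn("v2", tr[, 2], "int"),
        bcifColumn("v3", tr[, 3], "int")), nrow(tr))))
  }
  segIds <- vapply(result$segments, function(s) as.numeric(s$segment_id),
                   numeric(1))
  segMesh <- lapply(result$segments, function(s)
    as.numeric(unlist(s$mesh_ids) %||% numeric(0)))
  mapCat <- bcifCategory("_mesh_segment", list(
    bcifColumn("segment_id", rep(segIds, lengths(segMesh)), "int"),
    bcifColumn("mesh_id", unlist(segMesh) %||% numeric(0), "int")),
    sum(lengths(segMesh)))
  bcifSerialize(list(bcifBlock("mesh", c(cats, list(mapCat)))))
}

#' Decode a BinaryCIF response payload
#'
#' The reference decoder used by tests and offline clients: deserializes
#' the container and decodes every category's columns.
#'
#' @param bytes raw BinaryCIF payload.
#' @return named list of blocks; each block is a named list of
#'   categories; each category a named list of decoded columns plus
#'   `rowCount`.
#' @export
decodeResponse <- function(bytes) {
  blocks <- bcifDeserialize(bytes)
  out <- list()
  for (b in blocks) {
    cats <- list()
    for (cat in b$categories) {
      cols <- list(rowCount = cat$rowCount)
      for (col in cat$columns) cols[[col$name]] <- bcifDecodeColumn(col)
      cats[[cat$name]] <- cols
    }
    out[[b$header]] <- cats
  }
  out
}
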