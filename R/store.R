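# The internal database: one directory per (source, entry id) holding the
# volume and lattice pyramids as chunked compressed arrays plus
# metadata.json and annotations.json sidecars. Layout (a stable,
# versioned contract):
#   {root}/{source}/{entry_id}/volume/{factor}/
#   {root}/{source}/{entry_id}/segmentation/{lattice_id}/{factor}/
#   {root}/{source}/{entry_id}/metadata.json
#   {root}/{source}/{entry_id}/annotations.json

.FORMAT_VERSION <- "1"

#' Preprocess a volume (and optional segmentation) into an entry
#'
#' The preprocessor step: plans the pyramid levels from the volume
#' dimensions, builds the box-mean volume pyramid and majority-vote
#' lattice pyramids with per-level statistics/histograms, and bundles
#' them with the meshes and annotations into a
#' \linkS4class{MultiscaleEntry} ready for [saveEntry()]. Lattice levels
#' follow the volume's plan where the lattice dimensions permit.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param seg optional \linkS4class{SegmentationSet}.
#' @param source,entryId entry keys (sanitized to `[a-z0-9_-]`).
#' @param minExtent,maxTotalVoxels level-planning thresholds, see
#'   [planLevels()].
#' @return a \linkS4class{MultiscaleEntry}
#' @export
buildEntry <- function(grid, seg = NULL, source = "custom", entryId,
                       minExtent = 32L, maxTotalVoxels = 2^22) {
  factors <- planLevels(gridDims(grid), minExtent, maxTotalVoxels)
  vp <- buildPyramid(gridData(grid), factors, kind = "volume")
  lattices <- list(); hists <- list()
  meshesL <- list(); segs <- list(); segName <- ""
  if (!is.null(seg)) {
    rep <- validateAgainstVolume(seg, grid)
    if (nrow(rep))
      stopf("segmentation incompatible with volume: %s",
            paste(rep$kind, rep$detail, collapse = "; "))
    for (lt in seg@lattices) {
      lp <- buildPyramid(lt@data, factors, kind = "lattice")
      key <- as.character(lt@latticeId)
      lattices[[key]] <- lp$levels
      hists[[key]] <- lp$summaries
    }
    meshesL <- seg@meshes
    segs <- seg@segments
    segName <- seg@name
  }
  new("MultiscaleEntry",
      source = sanitizeKey(source), entryId = sanitizeKey(entryId),
      voxelSize = grid@voxelSize, origin = grid@origin,
      factors = factors, volume = vp$levels, volumeStats = vp$summaries,
      lattices = lattices, latticeHistograms = hists,
      meshes = meshesL, segments = segs, name = segName)
}

.entryDir <- function(root, source, entryId)
  file.path(root, sanitizeKey(source), sanitizeKey(entryId))

.segmentRecord <- function(s) {
  list(segment_id = s@segmentId, kind = s@kind,
       lattice_id = if (is.na(s@latticeId)) NULL else s@latticeId,
       label_value = if (is.na(s@labelValue)) NULL else s@labelValue,
       mesh_ids = as.integer(s@meshIds),
       name = s@name, description = s@description,
       colour = as.numeric(s@colour),
       external_references = s@externalReferences)
}

.segmentFromRecord <- function(r) {
  er <- if (length(r$external_references))
    do.call(rbind, lapply(r$external_references, function(row)
      data.frame(resource = row$resource, accession = row$accession,
                 label = row$label, stringsAsFactors = FALSE)))
  else data.frame(resource = character(), accession = character(),
                  label = character(), stringsAsFactors = FALSE)
  Segment(r$segment_id, r$kind,
          latticeId = if (is.null(r$lattice_id)) NA_integer_ else r$lattice_id,
          labelValue = if (is.null(r$label_value)) NA_integer_ else r$label_value,
          meshIds = unlist(r$mesh_ids) %||% integer(),
          name = r$name, description = r$description,
          colour = as.numeric(unlist(r$colour)),
          externalReferences = er)
}

#' Save a MultiscaleEntry into the database
#'
#' Writes every pyramid level as a chunked (default 64x64x64), zlib
#' compressed array in the Zarr v2 layout, and the metadata and
#' annotation records as JSON sidecars. Refuses to overwrite an existing
#' entry unless `overwrite = TRUE`.
#'
#' @param entry a \linkS4class{MultiscaleEntry}.
#' @param root database root directory (created if needed).
#' @param overwrite replace an existing entry.
#' @param chunk chunk dimensions.
#' @return the entry directory, invisibly.
#' @export
saveEntry <- function(entry, root, overwrite = FALSE, chunk = c(64L, 64L, 64L)) {
  validObject(entry)
  dir <- .entryDir(root, entry@source, entry@entryId)
  if (file.exists(dir)) {
    if (!overwrite) stopf("entry exists: %s/%s", entry@source, entry@entryId)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)

  for (f in names(entry@volume))
    zarrWriteArray(entry@volume[[f]], file.path(dir, "volume", f),
                   mode = "float32", chunk = chunk)
  for (lid in names(entry@lattices)) {
    maxLab <- max(0L, vapply(entry@lattices[[lid]], max, numeric(1)))
    mode <- latticeModeFor(maxLab)
    for (f in names(entry@lattices[[lid]]))
      zarrWriteArray(entry@lattices[[lid]][[f]],
                     file.path(dir, "segmentation", lid, f),
                     mode = mode, chunk = chunk)
  }

  d1 <- dim(entry@volume[["1"]])
  meta <- list(
    format_version = .FORMAT_VERSION,
    source = entry@source,
    entry_id = entry@entryId,
    name = entry@name,
    dims = d1,
    voxel_size = entry@voxelSize,
    origin = entry@origin,
    factors = entry@factors,
    level_dims = lapply(entry@volume, dim),
    volume_stats = lapply(entry@volumeStats, as.list),
    lattice_ids = as.integer(names(entry@lattices)),
    lattice_histograms = lapply(entry@latticeHistograms,
                                function(h) lapply(h, as.list)),
    mesh_info = lapply(entry@meshes, function(m)
      list(mesh_id = m@meshId, n_vertices = nrow(m@vertices),
           n_triangles = nrow(m@triangles)))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  jsonlite::write_json(list(name = entry@name,
                            segments = lapply(entry@segments, .segmentRecord)),
                       file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       dataframe = "rows")

  if (length(entry@meshes)) {
    mdir <- file.path(dir, "mesh")
    dir.create(mdir)
    for (m in entry@meshes) {
      g <- file.path(mdir, as.character(m@meshId))
      dir.create(g)
      writeBin(writeBin(as.numeric(t(m@vertices)), raw(), size = 8L,
                        endian = "little"), file.path(g, "vertices.f64"))
      writeBin(writeBin(as.integer(t(m@triangles)), raw(), size = 4L,
                        endian = "little"), file.path(g, "triangles.i32"))
    }
  }
  invisible(dir)
}

.readMeta <- function(dir) {
  p <- file.path(dir, "metadata.json")
  if (!file.exists(p)) stopf("corrupt entry: missing metadata.json in %s", dir)
  jsonlite::read_json(p, simplifyVector = FALSE)
}

.readAnnotations <- function(dir) {
  p <- file.path(dir, "annotations.json")
  if (!file.exists(p)) stopf("corrupt entry: missing annotations.json in %s", dir)
  jsonlite::read_json(p, simplifyVector = FALSE)
}

.checkEntryExists <- function(root, source, entryId) {
  dir <- .entryDir(root, source, entryId)
  if (!file.exists(file.path(dir, "metadata.json")))
    stopf("not found: %s/%s", source, entryId)
  dir
}

.loadMeshes <- function(dir, meta) {
  out <- list()
  for (mi in meta$mesh_info) {
    g <- file.path(dir, "mesh", as.character(mi$mesh_id))
    nv <- mi$n_vertices; nt <- mi$n_triangles
    vb <- readBin(file.path(g, "vertices.f64"), "raw", 8 * 3 * nv)
    tb <- readBin(file.path(g, "triangles.i32"), "raw", 4 * 3 * nt)
    v <- matrix(readBin(vb, "numeric", 3 * nv, size = 8L, endian = "little"),
                ncol = 3, byrow = TRUE)
    tr <- matrix(readBin(tb, "integer", 3 * nt, size = 4L, endian = "little"),
                 ncol = 3, byrow = TRUE)
    out[[length(out) + 1L]] <- Mesh(mi$mesh_id, v, tr)
  }
  out
}

#' Load a stored entry back into memory
#'
#' Reads every stored pyramid level, the meshes and the annotations and
#' reassembles the \linkS4class{MultiscaleEntry} bit-exactly. Metadata
#' and stored arrays are cross-validated; disagreement raises a corrupt
#' entry error. For budgeted partial reads use [queryBox()], which only
#' touches intersecting chunks.
#'
#' @param source,entryId entry keys.
#' @param root database root.
#' @return a \linkS4class{MultiscaleEntry}
#' @export
loadEntry <- function(source, entryId, root) {
  dir <- .checkEntryExists(root, source, entryId)
  meta <- .readMeta(dir)
  factors <- as.integer(unlist(meta$factors))
  vol <- list(); vstats <- list()
  for (f in as.character(factors)) {
    vdir <- file.path(dir, "volume", f)
    if (!file.exists(file.path(vdir, ".zarray")))
      stopf("corrupt entry: metadata lists factor %s but volume array missing", f)
    vol[[f]] <- zarrReadArray(vdir)
    vstats[[f]] <- unlist(meta$volume_stats[[f]])
    if (!identical(as.integer(unlist(meta$level_dims[[f]])), dim(vol[[f]])))
      stopf("corrupt entry: level %s dims disagree with metadata", f)
  }
  lattices <- list(); hists <- list()
  for (lid in as.character(unlist(meta$lattice_ids))) {
    ldirs <- file.path(dir, "segmentation", lid)
    lev <- list()
    for (f in as.character(factors)) {
      adir <- file.path(ldirs, f)
      if (!file.exists(file.path(adir, ".zarray")))
        stopf("corrupt entry: lattice %s missing factor %s", lid, f)
      lev[[f]] <- zarrReadArray(adir)
    }
    lattices[[lid]] <- lev
    hists[[lid]] <- lapply(meta$lattice_histograms[[lid]],
                           function(h) unlist(h))
  }
  ann <- .readAnnotations(dir)
  segs <- lapply(ann$segments, .segmentFromRecord)
  new("MultiscaleEntry",
      source = sanitizeKey(source), entryId = sanitizeKey(entryId),
      voxelSize = as.numeric(unlist(meta$voxel_size)),
      origin = as.numeric(unlist(meta$origin)),
      factors = factors, volume = vol, volumeStats = vstats,
      lattices = lattices, latticeHistograms = hists,
      meshes = .loadMeshes(dir, meta), segments = segs,
      name = as.character(meta$name %||% ""))
}

#' List the entries of a database root
#'
#' Enumerates well-formed entries only (directories carrying a
#' metadata.json); stray directories are reported via a message, never an
#' error.
#'
#' @param root database root.
#' @return data.frame with columns `source`, `entry_id`, sorted
#'   lexicographically.
#' @export
listEntries <- function(root) {
  out <- data.frame(source = character(), entry_id = character(),
                    stringsAsFactors = FALSE)
  if (!dir.exists(root)) return(out)
  for (src in sort(list.dirs(root, recursive = FALSE, full.names = FALSE))) {
    for (id in sort(list.dirs(file.path(root, src), recursive = FALSE,
                              full.names = FALSE))) {
      if (file.exists(file.path(root, src, id, "metadata.json")))
        out <- rbind(out, data.frame(source = src, entry_id = id,
                                     stringsAsFactors = FALSE))
      else
        message(sprintf("skipping malformed entry directory %s/%s", src, id))
    }
  }
  out[order(out$source, out$entry_id), , drop = FALSE]
}

#' Remove an entry
#'
#' @param source,entryId entry keys.
#' @param root database root.
#' @return invisibly TRUE.
#' @export
removeEntry <- function(source, entryId, root) {
  dir <- .checkEntryExists(root, source, entryId)
  unlink(dir, recursive = TRUE)
  invisible(TRUE)
}
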