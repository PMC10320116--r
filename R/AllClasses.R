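#' @import methods
NULL

#' VolumeGrid: a 3D scalar field with a physical frame
#'
#' Canonical in-memory representation of a density/intensity map: a 3D
#' array indexed `[x, y, z]` together with the physical voxel size and the
#' position of voxel (0,0,0) in Angstroms, plus value statistics recomputed
#' from the data (header statistics of source files are never trusted).
#'
#' Values are doubles snapped to float32-representable numbers, so writing
#' and re-reading a mode-2 map is bit-exact.
#'
#' @slot data 3D numeric array, indexed `[x, y, z]`.
#' @slot voxelSize numeric(3), Angstrom per voxel along x, y, z.
#' @slot origin numeric(3), Angstrom position of voxel (0,0,0).
#' @slot stats named numeric: `min`, `max`, `mean`, `sigma` (population).
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation(
    data = "array",
    voxelSize = "numeric",
    origin = "numeric",
    stats = "numeric"
  )
)

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  st <- object@stats
  need <- c("min", "max", "mean", "sigma")
  if (!all(need %in% names(st))) {
    msg <- c(msg, "stats must contain min, max, mean, sigma")
  } else {
    if (!(st["min"] <= st["mean"] && st["mean"] <= st["max"]))
      msg <- c(msg, "stats must satisfy min <= mean <= max")
    if (st["sigma"] < 0)
      msg <- c(msg, "stats sigma must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Lattice: a 3D array of integer segmentation labels
#'
#' Label 0 is reserved for background/unassigned voxels. `mode` records the
#' declared element type of the source stream (e.g. "uint8"); behaviour is
#' type-invariant, the mode only controls serialized width.
#'
#' @slot latticeId integer identifier, unique within a SegmentationSet.
#' @slot data 3D integer array of non-negative labels, indexed `[x, y, z]`.
#' @slot mode character, one of "uint8", "uint16", "uint32".
#' @exportClass Lattice
setClass("Lattice",
  representation(
    latticeId = "integer",
    data = "array",
    mode = "character"
  )
)

setValidity("Lattice", function(object) {
  msg <- character()
  if (length(object@latticeId) != 1L)
    msg <- c(msg, "latticeId must be a single integer")
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(object@data < 0))
    msg <- c(msg, "labels must be non-negative (0 = background)")
  if (!object@mode %in% c("uint8", "uint16", "uint32"))
    msg <- c(msg, "mode must be uint8, uint16 or uint32")
  if (length(msg)) msg else TRUE
})

#' Mesh: a triangle mesh bounding a segmented object
#'
#' Vertex coordinates are in Angstroms in the same physical frame as the
#' volume. Triangle indices are 0-based (matching the wire formats); R code
#' indexing `vertices` must add 1.
#'
#' @slot meshId integer identifier.
#' @slot vertices numeric matrix, n x 3.
#' @slot triangles integer matrix, m x 3, 0-based indices into vertices.
#' @exportClass Mesh
setClass("Mesh",
  representation(
    meshId = "integer",
    vertices = "matrix",
    triangles = "matrix"
  )
)

setValidity("Mesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
  tr <- object@triangles
  if (nrow(tr)) {
    if (any(tr < 0L) || any(tr >= nrow(object@vertices)))
      msg <- c(msg, "triangle indices must lie in [0, vertex count)")
    degen <- tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]
    if (any(degen))
      msg <- c(msg, "degenerate triangles (repeated vertex index) not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Segment: one annotated segmentation region
#'
#' A segment is either lattice-kind (a label value within one lattice) or
#' mesh-kind (one or more meshes). It carries the biological annotation:
#' name, free-text description, an RGBA colour in [0,1], and external
#' database references.
#'
#' @slot segmentId integer, unique within a SegmentationSet.
#' @slot kind "lattice" or "mesh".
#' @slot latticeId integer (lattice kind; NA otherwise).
#' @slot labelValue integer label > 0 (lattice kind; NA otherwise).
#' @slot meshIds integer vector (mesh kind; empty otherwise).
#' @slot name,description character.
#' @slot colour numeric(4) RGBA in [0,1].
#' @slot externalReferences data.frame with columns resource, accession, label.
#' @exportClass Segment
setClass("Segment",
  representation(
    segmentId = "integer",
    kind = "character",
    latticeId = "integer",
    labelValue = "integer",
    meshIds = "integer",
    name = "character",
    description = "character",
    colour = "numeric",
    externalReferences = "data.frame"
  )
)

setValidity("Segment", function(object) {
  msg <- character()
  if (!object@kind %in% c("lattice", "mesh"))
    msg <- c(msg, "kind must be 'lattice' or 'mesh'")
  if (object@kind == "lattice") {
    if (is.na(object@latticeId)) msg <- c(msg, "lattice segment needs latticeId")
    if (is.na(object@labelValue) || object@labelValue <= 0L)
      msg <- c(msg, "lattice segment needs labelValue > 0")
  }
  if (object@kind == "mesh" && length(object@meshIds) == 0L)
    msg <- c(msg, "mesh segment needs at least one meshId")
  if (length(object@colour) != 4L || any(object@colour < 0) ||
      any(object@colour > 1))
    msg <- c(msg, "colour must be RGBA in [0,1]")
  er <- object@externalReferences
  if (!all(c("resource", "accession", "label") %in% names(er)))
    msg <- c(msg, "externalReferences needs resource, accession, label columns")
  if (length(msg)) msg else TRUE
})

#' SegmentationSet: lattices and/or meshes plus annotated segments
#'
#' The in-memory model of one EMDB-SFF file: volumetric label lattices,
#' triangle meshes, and the segments that reference them with their
#' biological annotations. Validity enforces that every cross-reference
#' (latticeId, meshId) resolves and segment ids are unique.
#'
#' @slot name character.
#' @slot lattices list of \linkS4class{Lattice}.
#' @slot meshes list of \linkS4class{Mesh}.
#' @slot segments list of \linkS4class{Segment}.
#' @exportClass SegmentationSet
setClass("SegmentationSet",
  representation(
    name = "character",
    lattices = "list",
    meshes = "list",
    segments = "list"
  )
)

setValidity("SegmentationSet", function(object) {
  msg <- character()
  lids <- vapply(object@lattices, function(l) l@latticeId, integer(1))
  mids <- vapply(object@meshes, function(m) m@meshId, integer(1))
  sids <- vapply(object@segments, function(s) s@segmentId, integer(1))
  if (anyDuplicated(lids)) msg <- c(msg, "duplicate latticeId")
  if (anyDuplicated(mids)) msg <- c(msg, "duplicate meshId")
  if (anyDuplicated(sids)) msg <- c(msg, "duplicate segmentId")
  for (s in object@segments) {
    if (s@kind == "lattice" && !(s@latticeId %in% lids))
      msg <- c(msg, sprintf("segment %d references missing lattice %d",
                            s@segmentId, s@latticeId))
    if (s@kind == "mesh" && !all(s@meshIds %in% mids))
      msg <- c(msg, sprintf("segment %d references missing mesh", s@segmentId))
  }
  if (length(msg)) msg else TRUE
})

#' MultiscaleEntry: one preprocessed database entry
#'
#' Everything the store persists for one (source, entry id) pair: the
#' volume pyramid with per-level statistics, zero or more label-lattice
#' pyramids with per-level histograms, meshes, segments, and the physical
#' frame. Pyramid levels are named lists keyed by the (character) factor.
#'
#' @slot source character key, e.g. "emdb", "custom".
#' @slot entryId character key.
#' @slot voxelSize,origin numeric(3).
#' @slot factors integer vector of pyramid factors (1, 2, 4, ...).
#' @slot volume named list: factor -> 3D array.
#' @slot volumeStats named list: factor -> named numeric stats.
#' @slot lattices named list: latticeId -> (factor -> 3D integer array).
#' @slot latticeHistograms named list: latticeId -> (factor -> named counts).
#' @slot meshes list of \linkS4class{Mesh}.
#' @slot segments list of \linkS4class{Segment}.
#' @slot name character dataset name.
#' @exportClass MultiscaleEntry
setClass("MultiscaleEntry",
  representation(
    source = "character",
    entryId = "character",
    voxelSize = "numeric",
    origin = "numeric",
    factors = "integer",
    volume = "list",
    volumeStats = "list",
    lattices = "list",
    latticeHistograms = "list",
    meshes = "list",
    segments = "list",
    name = "character"
  )
)

setValidity("MultiscaleEntry", function(object) {
  msg <- character()
  fk <- as.character(object@factors)
  if (!identical(sort(names(object@volume)), sort(fk)))
    msg <- c(msg, "volume levels must match declared factors")
  if (!identical(sort(names(object@volumeStats)), sort(fk)))
    msg <- c(msg, "volumeStats must match declared factors")
  for (lid in names(object@lattices)) {
    if (!all(names(object@lattices[[lid]]) %in% fk))
      msg <- c(msg, sprintf("lattice %s has levels outside the volume plan", lid))
  }
  if (length(msg)) msg else TRUE
})

#' BoxQuery: a half-open voxel-space region plus a point budget
#'
#' Box coordinates are 0-based, half-open, in original-resolution
#' (factor 1) voxel space. `maxPoints` is the largest number of values the
#' response may contain; the server satisfies it by choosing a coarser
#' pyramid level.
#'
#' @slot source,entryId character entry keys.
#' @slot channel "volume" or "lattice".
#' @slot latticeId integer (lattice channel only).
#' @slot lo,hi integer(3), half-open box `[lo, hi)`.
#' @slot maxPoints positive integer budget.
#' @exportClass BoxQuery
setClass("BoxQuery",
  representation(
    source = "character",
    entryId = "character",
    channel = "character",
    latticeId = "integer",
    lo = "integer",
    hi = "integer",
    maxPoints = "numeric"
  )
)

setValidity("BoxQuery", function(object) {
  msg <- character()
  if (!object@channel %in% c("volume", "lattice"))
    msg <- c(msg, "channel must be 'volume' or 'lattice'")
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    msg <- c(msg, "lo and hi must have length 3")
  if (any(object@lo < 0L)) msg <- c(msg, "lo must be non-negative")
  if (length(object@maxPoints) != 1L || object@maxPoints <= 0)
    msg <- c(msg, "maxPoints must be a positive number")
  if (length(msg)) msg else TRUE
})

#' SliceResult: the server's answer to a box query
#'
#' @slot factor the chosen downsampling factor.
#' @slot levelLo,levelHi integer(3), the half-open level-space box returned.
#' @slot values 3D array (floats for volume, labels for lattice).
#' @slot stats per-level stats (volume) or label histogram (lattice).
#' @slot budgetExceeded TRUE when even the coarsest level overruns maxPoints.
#' @slot channel "volume" or "lattice"; @slot latticeId integer or NA.
#' @exportClass SliceResult
setClass("SliceResult",
  representation(
    factor = "integer",
    levelLo = "integer",
    levelHi = "integer",
    values = "array",
    stats = "ANY",
    budgetExceeded = "logical",
    channel = "character",
    latticeId = "integer"
  )
)

setValidity("SliceResult", function(object) {
  d <- object@levelHi - object@levelLo
  if (!identical(dim(object@values), as.integer(d)))
    "value array dims must equal the level-space box dims" else TRUE
})
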