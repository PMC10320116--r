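#' @rdname VolumeGrid-class
#' @export
setMethod("gridData", "VolumeGrid", function(x) x@data)

#' @rdname VolumeGrid-class
#' @export
setMethod("gridDims", "VolumeGrid", function(x) dim(x@data))

#' @rdname Lattice-class
#' @param x a Lattice
#' @export
setMethod("gridData", "Lattice", function(x) x@data)

#' @rdname Lattice-class
#' @export
setMethod("gridDims", "Lattice", function(x) dim(x@data))

#' @rdname VolumeGrid-class
#' @export
setMethod("voxelSize", "VolumeGrid", function(x) x@voxelSize)

#' @rdname VolumeGrid-class
#' @export
setMethod("gridOrigin", "VolumeGrid", function(x) x@origin)

#' @rdname VolumeGrid-class
#' @export
setMethod("gridStats", "VolumeGrid", function(x) x@stats)

#' @rdname SegmentationSet-class
#' @export
setMethod("latticeList", "SegmentationSet", function(x) x@lattices)

#' @rdname SegmentationSet-class
#' @export
setMethod("meshList", "SegmentationSet", function(x) x@meshes)

#' @rdname SegmentationSet-class
#' @export
setMethod("segmentList", "SegmentationSet", function(x) x@segments)

#' @rdname Mesh-class
#' @export
setMethod("meshVertices", "Mesh", function(x) x@vertices)

#' @rdname Mesh-class
#' @export
setMethod("meshTriangles", "Mesh", function(x) x@triangles)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (A): %s\n",
              paste(format(object@voxelSize, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (A):     %s\n",
              paste(format(object@origin, digits = 4), collapse = ", ")))
  st <- object@stats
  cat(sprintf("  values: min %.4g  max %.4g  mean %.4g  sigma %.4g\n",
              st["min"], st["max"], st["mean"], st["sigma"]))
})

setMethod("show", "Lattice", function(object) {
  d <- dim(object@data)
  labs <- sort(unique(as.vector(object@data)))
  cat(sprintf("Lattice #%d  %d x %d x %d  mode %s  labels {%s}\n",
              object@latticeId, d[1], d[2], d[3], object@mode,
              paste(utils::head(labs, 10), collapse = ",")))
})

setMethod("show", "Mesh", function(object) {
  cat(sprintf("Mesh #%d  %d vertices, %d triangles\n",
              object@meshId, nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "SegmentationSet", function(object) {
  cat(sprintf("SegmentationSet '%s': %d lattice(s), %d mesh(es), %d segment(s)\n",
              object@name, length(object@lattices), length(object@meshes),
              length(object@segments)))
  for (s in object@segments) {
    ref <- if (s@kind == "lattice")
      sprintf("lattice %d value %d", s@latticeId, s@labelValue)
    else sprintf("mesh %s", paste(s@meshIds, collapse = ","))
    cat(sprintf("  segment %d [%s] '%s' (%s)\n", s@segmentId, s@kind, s@name, ref))
  }
})

setMethod("show", "MultiscaleEntry", function(object) {
  cat(sprintf("MultiscaleEntry %s/%s\n", object@source, object@entryId))
  cat(sprintf("  factors: %s\n", paste(object@factors, collapse = ", ")))
  d <- dim(object@volume[["1"]])
  cat(sprintf("  volume: %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  lattices: %s  meshes: %d  segments: %d\n",
              if (length(object@lattices))
                paste(names(object@lattices), collapse = ", ") else "none",
              length(object@meshes), length(object@segments)))
})

setMethod("show", "SliceResult", function(object) {
  cat(sprintf("SliceResult [%s] factor %d  box [%s) - [%s)  %s values%s\n",
              object@channel, object@factor,
              paste(object@levelLo, collapse = ","),
              paste(object@levelHi, collapse = ","),
              length(object@values),
              if (object@budgetExceeded) "  (budget exceeded)" else ""))
})
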