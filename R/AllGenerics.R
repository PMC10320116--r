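#' @rdname VolumeGrid-class
#' @param x a volseg object
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("gridStats", function(x) standardGeneric("gridStats"))

#' @rdname SegmentationSet-class
#' @param x a SegmentationSet
#' @export
setGeneric("latticeList", function(x) standardGeneric("latticeList"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("meshList", function(x) standardGeneric("meshList"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("segmentList", function(x) standardGeneric("segmentList"))

#' @rdname Mesh-class
#' @param x a Mesh
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname Mesh-class
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))
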