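# Downsampling pyramids: box-mean for intensities, majority vote for
# labels. Pyramids are built by repeated halving; the level plan decides
# how many halvings a grid gets.

#' Plan the downsampling levels for a grid
#'
#' Returns the ordered pyramid factors `1, 2, 4, ...`. Starting from the
#' original (factor 1), a further level is added while the previous
#' level's total voxel count is still at least `maxTotalVoxels` and
#' halving again keeps the largest dimension at least `minExtent`. Factor
#' 1 is always included, so grids already below the thresholds get a
#' single-level plan.
#'
#' @param dims integer(3) grid dimensions.
#' @param minExtent smallest useful extent of the coarsest level (voxels).
#' @param maxTotalVoxels per-level voxel count above which another level
#'   is added.
#' @return integer vector of factors, strictly increasing, starting at 1.
#' @examples
#' planLevels(c(64, 64, 64), minExtent = 4, maxTotalVoxels = 4096)
#' @export
planLevels <- function(dims, minExtent = 32L, maxTotalVoxels = 2^22) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L)) stopf("dims must be 3 positive integers")
  if (minExtent < 1L) stopf("minExtent must be >= 1")
  factors <- 1L
  f <- 1L
  repeat {
    levelDims <- ceiling(dims / f)
    if (prod(levelDims) < maxTotalVoxels) break
    nextDims <- ceiling(dims / (f * 2L))
    # never shrink the largest axis below minExtent, and never halve a
    # grid whose largest axis would collapse to a single voxel
    if (max(nextDims) < max(minExtent, 2L)) break
    f <- f * 2L
    factors <- c(factors, f)
  }
  factors
}

# Map each input index (1-based) along one axis to its output block index.
.blockIndex <- function(n) (seq_len(n) - 1L) %/% 2L + 1L

#' Downsample a volume by factor 2 (box mean)
#'
#' Each output voxel is the arithmetic mean of its 2x2x2 input block;
#' output dimensions are `ceiling(dims / 2)`. Partial blocks at odd-sized
#' boundaries average only the voxels that exist (no padding values are
#' invented).
#'
#' @param data 3D numeric array.
#' @return 3D numeric array of dimension `ceiling(dim(data) / 2)`.
#' @export
downsampleVolume <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stopf("expected a 3D array")
  if (any(d == 0L) || length(data) == 0L) stopf("empty grid")
  od <- as.integer(ceiling(d / 2))
  bx <- .blockIndex(d[1]); by <- .blockIndex(d[2]); bz <- .blockIndex(d[3])
  g <- bx[slice.index(data, 1)] +
    (by[slice.index(data, 2)] - 1L) * od[1] +
    (bz[slice.index(data, 3)] - 1L) * od[1] * od[2]
  sums <- rowsum(as.numeric(data), group = as.vector(g))
  counts <- rowsum(rep(1, length(data)), group = as.vector(g))
  out <- as.numeric(sums / counts)   # rowsum sorts numeric groups ascending
  array(out, dim = od)
}

#' Downsample a label lattice by factor 2 (majority vote)
#'
#' Each output voxel takes the most frequent label of its 2x2x2 block,
#' ties broken by the smallest label value; background 0 participates like
#' any other label. Partial boundary blocks vote over existing voxels
#' only. The output label set is therefore always a subset of the input's.
#'
#' @param labels 3D integer array of non-negative labels.
#' @return 3D integer array of dimension `ceiling(dim(labels) / 2)`.
#' @export
downsampleLattice <- function(labels) {
  d <- dim(labels)
  if (is.null(d) || length(d) != 3L) stopf("expected a 3D array")
  if (any(d == 0L) || length(labels) == 0L) stopf("empty grid")
  od <- as.integer(ceiling(d / 2))
  bx <- .blockIndex(d[1]); by <- .blockIndex(d[2]); bz <- .blockIndex(d[3])
  g <- bx[slice.index(labels, 1)] +
    (by[slice.index(labels, 2)] - 1L) * od[1] +
    (bz[slice.index(labels, 3)] - 1L) * od[1] * od[2]
  v <- as.integer(labels)
  # Count (block, label) pairs, then pick per block the label with the
  # highest count; ties resolve to the smallest label because ordering is
  # by count descending then label ascending.
  ord <- order(as.vector(g), v)
  gs <- as.vector(g)[ord]; vs <- v[ord]
  r <- rle(paste(gs, vs))
  firsts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  blk <- gs[firsts]; lab <- vs[firsts]; cnt <- r$lengths
  pick <- order(blk, -cnt, lab)
  keep <- !duplicated(blk[pick])
  chosen <- lab[pick][keep]
  names(chosen) <- blk[pick][keep]
  out <- chosen[as.character(seq_len(prod(od)))]
  array(as.integer(out), dim = od)
}

#' Build a downsampling pyramid with per-level summaries
#'
#' Level 1 is the input itself (bit-identical); each further level is the
#' factor-2 downsampling of the previous one. For volumes (`kind =
#' "volume"`) the box-mean kernel is used and per-level statistics are
#' computed; for lattices (`kind = "lattice"`) majority vote is used and
#' per-level label histograms are computed.
#'
#' @param data 3D array (intensities or labels).
#' @param factors integer vector from [planLevels()].
#' @param kind "volume" or "lattice".
#' @return list with `levels` (named list factor -> array) and `summaries`
#'   (named list factor -> stats or histogram).
#' @export
buildPyramid <- function(data, factors, kind = c("volume", "lattice")) {
  kind <- match.arg(kind)
  factors <- as.integer(factors)
  if (factors[1] != 1L || is.unsorted(factors, strictly = TRUE))
    stopf("factors must be strictly increasing and start at 1")
  levels <- list(); summaries <- list()
  current <- data
  currentF <- 1L
  for (f in factors) {
    while (currentF < f) {
      current <- if (kind == "volume") asFloat32(downsampleVolume(current))
                 else downsampleLattice(current)
      currentF <- currentF * 2L
    }
    if (currentF != f) stopf("factor %d is not a power-of-two refinement", f)
    levels[[as.character(f)]] <- current
    summaries[[as.character(f)]] <-
      if (kind == "volume") computeStats(current) else labelHistogram(current)
  }
  list(levels = levels, summaries = summaries)
}
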