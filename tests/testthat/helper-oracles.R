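# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (triple loops, exhaustive search) so they cannot
# share a defect with the vectorized implementations they check.

randomGrid <- function(dims, seed, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
  set.seed(seed)
  VolumeGrid(array(rnorm(prod(dims)), dim = dims),
             voxelSize = voxelSize, origin = origin)
}

randomLabels <- function(dims, seed, maxLabel = 4L) {
  set.seed(seed)
  array(sample(0:maxLabel, prod(dims), replace = TRUE), dim = dims)
}

# Block-mean downsampling by explicit loops over output voxels.
bruteBlockMean <- function(data) {
  d <- dim(data)
  od <- ceiling(d / 2)
  out <- array(0, dim = od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (k in seq_len(od[3])) {
    xs <- (2 * i - 1):min(2 * i, d[1])
    ys <- (2 * j - 1):min(2 * j, d[2])
    zs <- (2 * k - 1):min(2 * k, d[3])
    out[i, j, k] <- mean(data[xs, ys, zs])
  }
  out
}

# Majority vote with smallest-label tie break by per-block histograms.
bruteBlockMode <- function(labels) {
  d <- dim(labels)
  od <- ceiling(d / 2)
  out <- array(0L, dim = od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (k in seq_len(od[3])) {
    xs <- (2 * i - 1):min(2 * i, d[1])
    ys <- (2 * j - 1):min(2 * j, d[2])
    zs <- (2 * k - 1):min(2 * k, d[3])
    block <- as.vector(labels[xs, ys, zs])
    tab <- table(block)
    best <- names(tab)[tab == max(tab)]
    out[i, j, k] <- min(as.integer(best))
  }
  out
}

# Exhaustive minimal-factor search for the level chooser.
bruteChooseLevel <- function(boxDims, factors, maxPoints) {
  for (f in sort(factors)) {
    if (prod(ceiling(boxDims / f)) <= maxPoints)
      return(list(factor = f, budgetExceeded = FALSE))
  }
  list(factor = max(factors), budgetExceeded = TRUE)
}

# Count of integer points strictly inside a sphere, by enumeration.
bruteDigitalSphereCount <- function(radius) {
  r <- ceiling(radius)
  n <- 0L
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if (x^2 + y^2 + z^2 < radius^2) n <- n + 1L
  n
}

# A small complete entry (volume + lattice + mesh) stored under a temp
# root; used by store/query tests.
makeStoredFixture <- function(root, dims = c(32L, 32L, 32L), seed = 7L,
                              nSegments = 2L, source = "emdb", id = "e1",
                              minExtent = 4L, maxTotalVoxels = 4096) {
  grid <- makeBlobVolume(dims, nBlobs = 2L, seed = seed, noiseSigma = 0.05)
  seg <- makeSphereSegmentation(grid, nSegments, seed + 1L,
                                radius = max(2, min(dims) %/% 8))
  ico <- makeIcosphere(1L)
  box <- gridDims(grid) * voxelSize(grid)
  mesh <- Mesh(1L, meshVertices(ico) * (min(box) / 4) +
                 matrix(box / 2, nrow = nrow(meshVertices(ico)), ncol = 3,
                        byrow = TRUE),
               meshTriangles(ico))
  segAll <- SegmentationSet(
    name = "fixture", lattices = latticeList(seg), meshes = list(mesh),
    segments = c(segmentList(seg),
                 list(Segment(nSegments + 1L, "mesh", meshIds = 1L,
                              name = "shell"))))
  entry <- buildEntry(grid, segAll, source, id,
                      minExtent = minExtent, maxTotalVoxels = maxTotalVoxels)
  saveEntry(entry, root)
  list(grid = grid, seg = segAll, entry = entry)
}
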