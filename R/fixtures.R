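# Deterministic synthetic data: Gaussian-blob volumes, digital-sphere
# lattice segmentations with annotations, icosphere meshes, and matched
# map/.hff input pairs. Every generator is fully determined by its seed
# (a private RNG stream is used and the caller's RNG state restored), so
# the whole pipeline is testable without downloads.

#' Synthetic volume: sum of Gaussian blobs plus noise
#'
#' Draws `nBlobs` isotropic Gaussians with random integer-voxel centers,
#' amplitudes in [0.5, 2] and widths in [min(dims)/10, min(dims)/5],
#' sums them on the grid and adds i.i.d. Gaussian noise. With
#' `nBlobs = 0` and `noiseSigma = 0` the grid is all zeros.
#'
#' @param dims integer(3), at least 4 per axis.
#' @param nBlobs number of Gaussians.
#' @param seed integer; fully determines the output.
#' @param noiseSigma standard deviation of the additive noise.
#' @param voxelSize physical voxel size in Angstrom.
#' @return a \linkS4class{VolumeGrid}; attribute `centers` carries the
#'   drawn blob center voxels (0-based) for construction oracles.
#' @export
makeBlobVolume <- function(dims = c(64L, 64L, 64L), nBlobs = 3L, seed = 1L,
                           noiseSigma = 0.05, voxelSize = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (any(dims < 4L)) stopf("dims must be >= 4 per axis")
  withSeed(seed, {
    vol <- array(0, dim = dims)
    centers <- matrix(0L, nrow = nBlobs, ncol = 3)
    x <- seq_len(dims[1]) - 1L
    y <- seq_len(dims[2]) - 1L
    z <- seq_len(dims[3]) - 1L
    for (b in seq_len(nBlobs)) {
      centre <- c(sample(dims[1], 1L), sample(dims[2], 1L),
                  sample(dims[3], 1L)) - 1L
      centers[b, ] <- centre
      amp <- stats::runif(1, 0.5, 2)
      width <- stats::runif(1, min(dims) / 10, min(dims) / 5)
      gx <- exp(-(x - centre[1])^2 / (2 * width^2))
      gy <- exp(-(y - centre[2])^2 / (2 * width^2))
      gz <- exp(-(z - centre[3])^2 / (2 * width^2))
      vol <- vol + amp * (gx %o% gy %o% gz)
    }
    if (noiseSigma > 0)
      vol <- vol + array(stats::rnorm(prod(dims), 0, noiseSigma), dim = dims)
    g <- VolumeGrid(vol, voxelSize = voxelSize)
    attr(g, "centers") <- centers
    g
  })
}

# Voxels (0-based integer coordinates) strictly inside a digital sphere:
# membership is voxel center within radius, strict <.
.digitalSphereMask <- function(dims, centre, radius) {
  x <- (seq_len(dims[1]) - 1L) - centre[1]
  y <- (seq_len(dims[2]) - 1L) - centre[2]
  z <- (seq_len(dims[3]) - 1L) - centre[3]
  d2 <- (x^2) %o% rep(1, dims[2]) %o% rep(1, dims[3]) +
    rep(1, dims[1]) %o% (y^2) %o% rep(1, dims[3]) +
    rep(1, dims[1]) %o% rep(1, dims[2]) %o% (z^2)
  d2 < radius^2
}

#' Synthetic lattice segmentation: non-overlapping digital spheres
#'
#' Places `nSegments` digital spheres (voxel center strictly within
#' radius) labeled 1..n on a lattice matching the grid, with bounded
#' random retries to avoid overlap. Each segment gets a generated name
#' (`segment_k`), the deterministic palette colour for its id, and one
#' synthetic external reference (resource "GO").
#'
#' @param grid a \linkS4class{VolumeGrid} fixing the lattice dimensions.
#' @param nSegments number of spheres.
#' @param seed integer; fully determines the output.
#' @param radius sphere radius in voxels (default scales with the grid).
#' @return a \linkS4class{SegmentationSet} with one lattice and
#'   `nSegments` lattice-kind segments; attribute `spheres` records the
#'   drawn (center, radius) per segment.
#' @export
makeSphereSegmentation <- function(grid, nSegments = 3L, seed = 1L,
                                   radius = NULL) {
  dims <- gridDims(grid)
  if (is.null(radius)) radius <- max(2, min(dims) %/% 8)
  withSeed(seed, {
    labels <- array(0L, dim = dims)
    spheres <- matrix(0, nrow = nSegments, ncol = 4,
                      dimnames = list(NULL, c("cx", "cy", "cz", "r")))
    for (k in seq_len(nSegments)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        centre <- vapply(dims, function(d)
          sample(seq(ceiling(radius), d - 1 - ceiling(radius)), 1L), numeric(1))
        mask <- .digitalSphereMask(dims, centre, radius)
        if (!any(labels[mask] != 0L)) {
          labels[mask] <- k
          spheres[k, ] <- c(centre, radius)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("placement failed: could not place sphere %d without overlap", k)
    }
    segs <- lapply(seq_len(nSegments), function(k)
      Segment(k, "lattice", latticeId = 1L, labelValue = k,
              name = sprintf("segment_%d", k),
              description = sprintf("synthetic digital sphere %d", k),
              colour = defaultSegmentColour(k),
              externalReferences = data.frame(
                resource = "GO",
                accession = sprintf("GO:%07d", 1000000L + k),
                label = "synthetic term",
                stringsAsFactors = FALSE)))
    out <- SegmentationSet(name = "synthetic spheres",
                           lattices = list(Lattice(1L, labels)),
                           segments = segs)
    attr(out, "spheres") <- spheres
    out
  })
}

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  list(v = v / sqrt(1 + t^2), f = f)
}

#' Unit icosphere mesh
#'
#' Subdivides the unit icosahedron `subdivisions` times (each triangle
#' split into four, midpoints deduplicated and projected to the unit
#' sphere). Vertex and triangle counts follow V = 10 * 4^s + 2,
#' T = 20 * 4^s.
#'
#' @param subdivisions integer in 0..4.
#' @param meshId mesh identifier.
#' @return a \linkS4class{Mesh} with all vertices at unit radius.
#' @export
makeIcosphere <- function(subdivisions = 0L, meshId = 1L) {
  if (subdivisions < 0L || subdivisions > 4L)
    stopf("subdivisions must be in 0..4")
  ico <- .icosahedron()
  v <- ico$v; f <- ico$f
  for (s in seq_len(subdivisions)) {
    midCache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mget(key, envir = midCache, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[a + 1]] + vlist[[b + 1]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist) - 1L
      assign(key, idx, envir = midCache)
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
      nf[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
      nf[(i - 1) * 4 + 3, ] <- c(cc, ca, bc)
      nf[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  Mesh(meshId, v, f)
}

#' Write a matched synthetic map/.hff input pair
#'
#' Generates a blob volume and a sphere segmentation, adds one icosphere
#' mesh scaled into the volume's physical box (with a mesh-kind
#' segment), and writes a mode-2 MRC map plus an EMDB-SFF file — a valid
#' preprocessor input pair. Deterministic under `seed`.
#'
#' @param outDir output directory (created if needed).
#' @param dims,nBlobs,nSegments,seed,noiseSigma generator parameters.
#' @return list with `map` and `sff` file paths.
#' @export
makeEntryFiles <- function(outDir, dims = c(64L, 64L, 64L), nBlobs = 3L,
                           nSegments = 3L, seed = 1L, noiseSigma = 0.05) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- makeBlobVolume(dims, nBlobs, seed, noiseSigma)
  seg <- makeSphereSegmentation(grid, nSegments, seed + 1L)
  box <- gridDims(grid) * voxelSize(grid)
  ico <- makeIcosphere(1L, meshId = 1L)
  verts <- meshVertices(ico) * (min(box) / 4) +
    matrix(gridOrigin(grid) + box / 2, nrow = nrow(meshVertices(ico)),
           ncol = 3, byrow = TRUE)
  mesh <- Mesh(1L, verts, meshTriangles(ico))
  meshSeg <- Segment(nSegments + 1L, "mesh", meshIds = 1L,
                     name = sprintf("segment_%d", nSegments + 1L),
                     description = "synthetic icosphere shell",
                     colour = defaultSegmentColour(nSegments + 1L),
                     externalReferences = data.frame(
                       resource = "GO", accession = "GO:0000001",
                       label = "synthetic term", stringsAsFactors = FALSE))
  seg2 <- SegmentationSet(name = seg@name, lattices = seg@lattices,
                          meshes = list(mesh),
                          segments = c(seg@segments, list(meshSeg)))
  mapPath <- file.path(outDir, sprintf("fixture_%d.map", seed))
  sffPath <- file.path(outDir, sprintf("fixture_%d.hff", seed))
  writeMap(grid, mapPath, mode = 2L)
  writeSFF(seg2, sffPath)
  list(map = mapPath, sff = sffPath)
}
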