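makeLatticeSet <- function(seed = 1L, dims = c(4L, 4L, 4L), maxLabel = 2L) {
  labels <- randomLabels(dims, seed, maxLabel)
  segs <- lapply(seq_len(maxLabel), function(k)
    Segment(k, "lattice", latticeId = 1L, labelValue = k,
            name = sprintf("segment_%d", k), description = "test region",
            colour = c(0.2, 0.4, 0.6, 1.0),
            externalReferences = data.frame(
              resource = "GO", accession = sprintf("GO:%07d", k),
              label = "synthetic term", stringsAsFactors = FALSE)))
  SegmentationSet(name = "test", lattices = list(Lattice(1L, labels)),
                  segments = segs)
}

test_that("lattice segmentation round-trips with annotations and colours", {
  seg <- makeLatticeSet(seed = 1L)
  p <- withr::local_tempfile(fileext = ".hff")
  writeSFF(seg, p)
  back <- readSFF(p)
  expect_identical(gridData(latticeList(back)[[1]]),
                   gridData(latticeList(seg)[[1]]))
  expect_identical(latticeList(back)[[1]]@mode, latticeList(seg)[[1]]@mode)
  expect_length(segmentList(back), 2L)
  s1 <- segmentList(back)[[1]]
  expect_identical(s1@colour, c(0.2, 0.4, 0.6, 1.0))
  expect_identical(s1@name, "segment_1")
  expect_identical(s1@externalReferences$accession, "GO:0000001")
  # label histogram preserved exactly by serialization
  expect_identical(table(as.vector(gridData(latticeList(back)[[1]]))),
                   table(as.vector(gridData(latticeList(seg)[[1]]))))
})

test_that("an icosahedron mesh survives the container intact", {
  ico <- makeIcosphere(0L)
  seg <- SegmentationSet(name = "mesh", meshes = list(ico),
                         segments = list(Segment(1L, "mesh", meshIds = 1L,
                                                 name = "shell")))
  p <- withr::local_tempfile(fileext = ".hff")
  writeSFF(seg, p)
  back <- readSFF(p)
  m <- meshList(back)[[1]]
  expect_identical(nrow(meshVertices(m)), 12L)
  expect_identical(nrow(meshTriangles(m)), 20L)
  expect_equal(meshVertices(m), meshVertices(ico))
  expect_identical(meshTriangles(m), meshTriangles(ico))
})

test_that("an empty SegmentationSet round-trips", {
  p <- withr::local_tempfile(fileext = ".hff")
  writeSFF(SegmentationSet(name = "empty"), p)
  back <- readSFF(p)
  expect_length(latticeList(back), 0L)
  expect_length(meshList(back), 0L)
  expect_length(segmentList(back), 0L)
})

test_that("random label lattices round-trip exactly across modes", {
  for (seed in 1:10) {
    maxLabel <- c(2L, 300L, 70000L)[seed %% 3 + 1]   # uint8/16/32 widths
    labels <- randomLabels(c(5L, 4L, 3L), seed, maxLabel)
    seg <- SegmentationSet(name = "rt", lattices = list(Lattice(1L, labels)))
    p <- withr::local_tempfile(fileext = ".hff")
    writeSFF(seg, p)
    expect_identical(gridData(latticeList(readSFF(p))[[1]]), labels,
                     label = sprintf("seed %d", seed))
  }
})

test_that("invalid containers raise specific errors", {
  # dangling lattice reference
  seg <- makeLatticeSet(seed = 2L)
  p <- withr::local_tempfile(fileext = ".hff")
  writeSFF(seg, p)
  rhdf5::h5delete(p, "segment_list/1/three_d_volume/lattice_id")
  rhdf5::h5write(99L, p, "segment_list/1/three_d_volume/lattice_id")
  rhdf5::h5closeAll()
  expect_error(readSFF(p), "dangling lattice")

  # unknown lattice mode
  p2 <- withr::local_tempfile(fileext = ".hff")
  writeSFF(makeLatticeSet(seed = 3L), p2)
  rhdf5::h5delete(p2, "lattice_list/1/mode")
  rhdf5::h5write("float64", p2, "lattice_list/1/mode")
  rhdf5::h5closeAll()
  expect_error(readSFF(p2), "unsupported mode")

  # not an HDF5 file at all
  p3 <- withr::local_tempfile(fileext = ".hff")
  writeLines("not hdf5", p3)
  expect_error(readSFF(p3), "invalid SFF")

  # non-identity transform
  p4 <- withr::local_tempfile(fileext = ".hff")
  writeSFF(makeLatticeSet(seed = 4L), p4)
  rhdf5::h5delete(p4, "transform")
  rhdf5::h5write(cbind(2 * diag(3), c(0, 0, 0)), p4, "transform")
  rhdf5::h5closeAll()
  expect_error(readSFF(p4), "transform")

  # invariant violation refused at write time (slot surgery bypasses the
  # constructor's validity gate)
  bad <- makeLatticeSet(seed = 6L)
  bad@segments[[1]]@latticeId <- 9L
  expect_error(writeSFF(bad, withr::local_tempfile(fileext = ".hff")),
               "invalid segmentation")
})

test_that("segments lacking a colour get the deterministic palette default", {
  seg <- makeLatticeSet(seed = 5L)
  p <- withr::local_tempfile(fileext = ".hff")
  writeSFF(seg, p)
  rhdf5::h5delete(p, "segment_list/1/colour")
  rhdf5::h5closeAll()
  back <- readSFF(p)
  expect_identical(segmentList(back)[[1]]@colour, defaultSegmentColour(1L))
  expect_identical(segmentList(back)[[2]]@colour, c(0.2, 0.4, 0.6, 1.0))
})

test_that("validateAgainstVolume reports incompatibilities", {
  grid <- VolumeGrid(array(0, c(8, 8, 8)))
  ok <- SegmentationSet(lattices = list(Lattice(1L, array(0L, c(8, 8, 8)))))
  expect_identical(nrow(validateAgainstVolume(ok, grid)), 0L)

  small <- SegmentationSet(lattices = list(Lattice(1L, array(0L, c(4, 4, 4)))))
  rep1 <- validateAgainstVolume(small, grid)
  expect_identical(rep1$kind, "dims mismatch")

  mesh <- Mesh(1L, rbind(c(-5, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               rbind(c(0L, 1L, 2L)))
  outside <- SegmentationSet(meshes = list(mesh))
  rep2 <- validateAgainstVolume(outside, grid)
  expect_identical(rep2$kind, "vertex outside box")
})
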