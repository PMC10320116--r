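test_that("saveEntry lays out the documented storage tree", {
  root <- withr::local_tempdir()
  grid <- randomGrid(c(8, 8, 8), seed = 1)
  entry <- buildEntry(grid, NULL, "emdb", "demo",
                      minExtent = 2L, maxTotalVoxels = 256)
  expect_identical(entry@factors, c(1L, 2L))
  saveEntry(entry, root)
  base <- file.path(root, "emdb", "demo")
  expect_true(file.exists(file.path(base, "volume", "1", ".zarray")))
  expect_true(file.exists(file.path(base, "volume", "2", ".zarray")))
  expect_identical(list.files(file.path(base, "volume")), c("1", "2"))
  meta <- jsonlite::read_json(file.path(base, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$factors, c(1, 2))
  expect_identical(meta$format_version, "1")
  expect_true(file.exists(file.path(base, "annotations.json")))
})

test_that("storage round trip is bit-exact for arrays, stats and annotations", {
  root <- withr::local_tempdir()
  fx <- makeStoredFixture(root)
  back <- loadEntry("emdb", "e1", root)
  expect_identical(back@volume, fx$entry@volume)
  expect_identical(back@lattices, fx$entry@lattices)
  expect_identical(back@volumeStats, fx$entry@volumeStats)
  expect_identical(back@latticeHistograms, fx$entry@latticeHistograms)
  expect_identical(back@voxelSize, fx$entry@voxelSize)
  expect_identical(back@origin, fx$entry@origin)
  for (i in seq_along(fx$entry@segments)) {
    expect_identical(back@segments[[i]]@colour, fx$entry@segments[[i]]@colour)
    expect_identical(back@segments[[i]]@name, fx$entry@segments[[i]]@name)
    expect_identical(back@segments[[i]]@externalReferences,
                     fx$entry@segments[[i]]@externalReferences)
  }
  expect_equal(meshVertices(back@meshes[[1]]), meshVertices(fx$entry@meshes[[1]]))
  expect_identical(meshTriangles(back@meshes[[1]]),
                   meshTriangles(fx$entry@meshes[[1]]))
})

test_that("chunked box reads equal in-memory slices", {
  root <- withr::local_tempdir()
  grid <- randomGrid(c(70, 40, 50), seed = 9)    # spans multiple 32^3 chunks
  entry <- buildEntry(grid, NULL, "emdb", "chunky",
                      minExtent = 32L, maxTotalVoxels = 2^22)
  saveEntry(entry, root, chunk = c(32L, 32L, 32L))
  vdir <- file.path(root, "emdb", "chunky", "volume", "1")
  cases <- list(c(0, 0, 0, 8, 8, 8), c(0, 0, 0, 70, 40, 50),
                c(30, 30, 30, 34, 33, 50), c(69, 39, 49, 70, 40, 50),
                c(5, 31, 10, 40, 40, 33))
  for (b in cases) {
    got <- volseg:::zarrReadBox(vdir, b[1:3], b[4:6])
    expect_identical(got,
                     gridData(grid)[(b[1] + 1):b[4], (b[2] + 1):b[5],
                                    (b[3] + 1):b[6], drop = FALSE],
                     label = paste(b, collapse = ","))
  }
  expect_error(volseg:::zarrReadBox(vdir, c(0, 0, 0), c(0, 1, 1)),
               "empty region")
})

test_that("entry lifecycle: exists, list, remove, re-save", {
  root <- withr::local_tempdir()
  grid <- randomGrid(c(6, 6, 6), seed = 2)
  e <- buildEntry(grid, NULL, "custom", "a1")
  saveEntry(e, root)
  expect_error(saveEntry(e, root), "entry exists")
  expect_silent(saveEntry(e, root, overwrite = TRUE))

  e2 <- buildEntry(grid, NULL, "custom", "b2")
  saveEntry(e2, root)
  dir.create(file.path(root, "custom", "stray-not-an-entry"))
  got <- suppressMessages(listEntries(root))
  expect_identical(got$entry_id, c("a1", "b2"))

  removeEntry("custom", "a1", root)
  expect_identical(suppressMessages(listEntries(root))$entry_id, "b2")
  expect_error(removeEntry("custom", "a1", root), "not found")
  saveEntry(e, root)   # re-saving after removal succeeds
  expect_identical(suppressMessages(listEntries(root))$entry_id, c("a1", "b2"))

  expect_error(loadEntry("custom", "nope", root), "not found")
  expect_identical(nrow(listEntries(withr::local_tempdir())), 0L)
})

test_that("metadata/array disagreement is reported as corruption", {
  root <- withr::local_tempdir()
  grid <- randomGrid(c(8, 8, 8), seed = 3)
  entry <- buildEntry(grid, NULL, "emdb", "c1",
                      minExtent = 2L, maxTotalVoxels = 256)
  saveEntry(entry, root)
  unlink(file.path(root, "emdb", "c1", "volume", "2"), recursive = TRUE)
  expect_error(loadEntry("emdb", "c1", root), "corrupt entry")
})

test_that("two segmentations of one dataset live in separate entries", {
  root <- withr::local_tempdir()
  grid <- makeBlobVolume(c(16, 16, 16), 1L, 5L, 0.02)
  segA <- makeSphereSegmentation(grid, 1L, 10L, radius = 3)
  segB <- makeSphereSegmentation(grid, 2L, 20L, radius = 2)
  saveEntry(buildEntry(grid, segA, "emdb", "d-manual"), root)
  saveEntry(buildEntry(grid, segB, "emdb", "d-auto"), root)
  expect_identical(suppressMessages(listEntries(root))$entry_id,
                   c("d-auto", "d-manual"))
  a <- loadEntry("emdb", "d-manual", root)
  b <- loadEntry("emdb", "d-auto", root)
  expect_identical(a@volume, b@volume)   # same map
  expect_length(a@segments, 1L)
  expect_length(b@segments, 2L)
  expect_false(identical(a@lattices, b@lattices))
})
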