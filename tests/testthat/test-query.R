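test_that("chooseLevel picks the smallest factor within budget", {
  expect_identical(chooseLevel(c(64, 64, 64), c(1L, 2L, 4L), 3e5),
                   list(factor = 1L, budgetExceeded = FALSE))
  expect_identical(chooseLevel(c(64, 64, 64), c(1L, 2L, 4L), 1e5),
                   list(factor = 2L, budgetExceeded = FALSE))
  expect_identical(chooseLevel(c(64, 64, 64), c(1L, 2L), 10),
                   list(factor = 2L, budgetExceeded = TRUE))
  expect_error(chooseLevel(c(4, 4, 4), c(1L, 2L), 0), "invalid budget")
})

test_that("chooseLevel matches exhaustive search and is budget-monotone", {
  factorSets <- list(1L, c(1L, 2L), c(1L, 2L, 4L), c(1L, 2L, 4L, 8L))
  dims <- expand.grid(x = c(1, 3, 16, 33, 64), y = c(2, 8, 31, 64),
                      z = c(1, 7, 64))
  budgets <- c(1, 10, 100, 512, 4096, 32768, 262144, 1e6)
  n <- 0L
  for (fs in factorSets) for (i in seq_len(nrow(dims))) {
    prev <- NULL
    for (b in budgets) {
      d <- as.numeric(dims[i, ])
      got <- chooseLevel(d, fs, b)
      expect_identical(got$factor, as.integer(bruteChooseLevel(d, fs, b)$factor))
      expect_identical(got$budgetExceeded, bruteChooseLevel(d, fs, b)$budgetExceeded)
      if (!is.null(prev)) expect_lte(got$factor, prev)   # more budget, finer
      prev <- got$factor
      n <- n + 1L
    }
  }
  expect_gte(n, 480L)
})

root <- withr::local_tempdir()
fx <- makeStoredFixture(root, dims = c(32L, 32L, 32L), seed = 7L)
md <- getMetadata("emdb", "e1", root)

test_that("getMetadata echoes the stored documents and annotations", {
  expect_equal(unlist(md$metadata$factors), fx$entry@factors)
  expect_identical(md$metadata$entry_id, "e1")
  names <- vapply(md$annotations$segments, function(s) s$name, character(1))
  expect_setequal(names, c("segment_1", "segment_2", "shell"))
  expect_error(getMetadata("emdb", "missing", root), "not found")
})

test_that("full-box query at factor 1 returns the original data exactly", {
  r <- queryBox(BoxQuery("emdb", "e1", "volume", c(0, 0, 0), c(32, 32, 32),
                         1e6), root)
  expect_identical(r@factor, 1L)
  expect_false(r@budgetExceeded)
  expect_identical(r@values, gridData(fx$grid))

  rl <- queryBox(BoxQuery("emdb", "e1", "lattice", c(0, 0, 0), c(32, 32, 32),
                          1e6, latticeId = 1L), root)
  expect_identical(rl@values, gridData(latticeList(fx$seg)[[1]]))
})

test_that("sub-box queries slice like the in-memory array", {
  r <- queryBox(BoxQuery("emdb", "e1", "volume", c(0, 0, 0), c(2, 2, 2), 1e6),
                root)
  expect_identical(r@values, gridData(fx$grid)[1:2, 1:2, 1:2, drop = FALSE])
  # clamping: an oversized box is cut back to the grid
  r2 <- queryBox(BoxQuery("emdb", "e1", "volume", c(30, 30, 30), c(99, 99, 99),
                          1e6), root)
  expect_identical(r2@values, gridData(fx$grid)[31:32, 31:32, 31:32,
                                                drop = FALSE])
  expect_error(queryBox(BoxQuery("emdb", "e1", "volume", c(40, 0, 0),
                                 c(50, 2, 2), 1e6), root), "empty region")
  expect_error(queryBox(BoxQuery("emdb", "e1", "lattice", c(0, 0, 0),
                                 c(2, 2, 2), 1e6, latticeId = 42L), root),
               "not found")
})

test_that("tight budgets force coarser levels; level box covers the request", {
  r <- queryBox(BoxQuery("emdb", "e1", "volume", c(0, 0, 0), c(32, 32, 32),
                         512), root)
  expect_identical(r@factor, 4L)
  expect_lte(length(r@values), 512)
  expect_identical(r@levelHi - r@levelLo, dim(r@values))
  # level-space box maps floor/ceil from the request
  r2 <- queryBox(BoxQuery("emdb", "e1", "volume", c(3, 3, 3), c(9, 9, 9),
                          8), root)
  expect_identical(r2@levelLo, as.integer(c(3, 3, 3) %/% r2@factor))
  expect_identical(r2@levelHi, as.integer(ceiling(c(9, 9, 9) / r2@factor)))
  # budget below even the coarsest level
  r3 <- queryBox(BoxQuery("emdb", "e1", "volume", c(0, 0, 0), c(32, 32, 32),
                          2), root)
  expect_true(r3@budgetExceeded)
  expect_identical(r3@factor, max(fx$entry@factors))
})

test_that("constant volumes survive downsampled queries unchanged", {
  root2 <- withr::local_tempdir()
  grid <- VolumeGrid(array(1.5, c(16, 16, 16)))
  saveEntry(buildEntry(grid, NULL, "custom", "const",
                       minExtent = 2L, maxTotalVoxels = 64), root2)
  r <- queryBox(BoxQuery("custom", "const", "volume", c(0, 0, 0),
                         c(16, 16, 16), 64), root2)
  expect_gt(r@factor, 1L)
  expect_true(all(r@values == 1.5))
})

test_that("volume responses decode within the quantization bound", {
  r <- queryBox(BoxQuery("emdb", "e1", "volume", c(0, 0, 0), c(32, 32, 32),
                         1e6), root)
  dec <- decodeResponse(buildResponse(r, md$metadata, md$annotations))
  info <- dec$volume[["_volume_info"]]
  expect_identical(info$factor, 1)
  expect_identical(info$entry_id, "e1")
  data <- dec$volume[["_volume_data"]]
  expect_equal(data$rowCount, length(r@values))
  st <- gridStats(fx$grid)
  bound <- (st[["max"]] - st[["min"]]) / 508
  expect_lte(max(abs(data$values - as.numeric(r@values))), bound)
})

test_that("lattice responses decode exactly and carry the segment table", {
  rl <- queryBox(BoxQuery("emdb", "e1", "lattice", c(0, 0, 0), c(32, 32, 32),
                          1e6, latticeId = 1L), root)
  dec <- decodeResponse(buildResponse(rl, md$metadata, md$annotations))
  expect_identical(dec$segmentation[["_segmentation_data"]]$values,
                   as.numeric(rl@values))
  tab <- dec$segmentation[["_segment_table"]]
  expect_identical(tab$name, c("segment_1", "segment_2"))
  expect_identical(tab$label_value, c(1, 2))
  expect_equal(tab$colour_r[1], defaultSegmentColour(1L)[1], tolerance = 1e-4)
})

test_that("mesh queries return the stored geometry intact", {
  mp <- queryMeshes("emdb", "e1", root)
  expect_length(mp$meshes, 1L)
  m <- mp$meshes[[1]]
  expect_identical(nrow(meshVertices(m)), 42L)
  expect_identical(nrow(meshTriangles(m)), 80L)
  expect_true(all(meshTriangles(m) >= 0L & meshTriangles(m) < 42L))
  dec <- decodeResponse(buildResponse(mp, md$metadata, md$annotations))
  expect_identical(dec$mesh[["_mesh_vertex_1"]]$rowCount, 42)
  expect_identical(dec$mesh[["_mesh_triangle_1"]]$rowCount, 80)
  expect_equal(dec$mesh[["_mesh_vertex_1"]]$x, meshVertices(m)[, 1],
               tolerance = 1e-3)
  expect_equal(dec$mesh[["_mesh_triangle_1"]]$v1, meshTriangles(m)[, 1])
  seg <- dec$mesh[["_mesh_segment"]]
  expect_identical(seg$mesh_id, 1)

  rootNoMesh <- withr::local_tempdir()
  saveEntry(buildEntry(randomGrid(c(6, 6, 6), 1), NULL, "custom", "bare"),
            rootNoMesh)
  expect_error(queryMeshes("custom", "bare", rootNoMesh), "not found")
})

test_that("the HTTP handler maps queries and errors to status codes", {
  resp <- volseg:::.handleRequest(root, "GET", "/v1/emdb/e1/metadata")
  expect_identical(resp$status, 200L)
  parsed <- jsonlite::fromJSON(resp$body)
  expect_equal(parsed$metadata$entry_id, "e1")

  box <- volseg:::.handleRequest(root, "GET",
                                 "/v1/emdb/e1/volume/box/0,0,0/4,4,4",
                                 "max_points=100")
  expect_identical(box$status, 200L)
  dec <- decodeResponse(box$body)
  expect_identical(dec$volume[["_volume_data"]]$rowCount, 64)

  lat <- volseg:::.handleRequest(root, "GET",
                                 "/v1/emdb/e1/segmentation/1/box/0,0,0/32,32,32",
                                 "")
  expect_identical(lat$status, 200L)

  expect_identical(volseg:::.handleRequest(root, "GET",
                                           "/v1/emdb/nope/metadata")$status,
                   404L)
  expect_identical(volseg:::.handleRequest(root, "GET", "/v1/x")$status, 404L)
  expect_identical(volseg:::.handleRequest(root, "POST",
                                           "/v1/emdb/e1/metadata")$status,
                   405L)
  bad <- volseg:::.handleRequest(root, "GET",
                                 "/v1/emdb/e1/volume/box/0,0,0/4,4,4",
                                 "max_points=0")
  expect_identical(bad$status, 400L)
})
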