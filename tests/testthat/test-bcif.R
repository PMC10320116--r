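test_that("delta encoding is the prefix-sum inverse", {
  d <- encodeDelta(c(1, 2, 3))
  expect_equal(d$deltas, c(0, 1, 1))
  expect_equal(d$origin, 1)
  e <- encodeDelta(numeric(0))
  expect_equal(e$deltas, numeric(0))
  expect_equal(e$origin, 0)
  expect_equal(decodeDelta(e$deltas, e$origin), numeric(0))
  for (seed in 1:50) {
    set.seed(seed)
    v <- sample(-1e6:1e6, 100, replace = TRUE)
    d <- encodeDelta(v)
    expect_equal(decodeDelta(d$deltas, d$origin), as.numeric(v))
  }
})

test_that("run-length encoding collapses runs and restores them", {
  r <- encodeRLE(c(1, 1, 1, 2, 2))
  expect_equal(r$pairs, c(1, 3, 2, 2))
  expect_equal(encodeRLE(5)$pairs, c(5, 1))
  for (seed in 1:50) {
    set.seed(seed)
    v <- rep(sample(0:5, 20, replace = TRUE), times = sample(1:10, 20, replace = TRUE))
    r <- encodeRLE(v)
    expect_equal(decodeRLE(r$pairs, r$srcSize), as.numeric(v))
  }
})

test_that("integer packing emits bound runs plus remainder", {
  expect_equal(packIntegers(1200, 1, TRUE), c(255, 255, 255, 255, 180))
  expect_equal(packIntegers(100, 1, TRUE), 100)
  expect_error(packIntegers(1, 3, TRUE), "invalid packing")
  expect_error(packIntegers(-1, 1, TRUE), "invalid packing")
  for (seed in 1:25) for (bc in c(1L, 2L)) {
    set.seed(seed + bc)
    v <- sample(-1e5:1e5, 50, replace = TRUE)
    expect_equal(unpackIntegers(packIntegers(v, bc, FALSE), bc, FALSE),
                 as.numeric(v))
    u <- abs(v)
    expect_equal(unpackIntegers(packIntegers(u, bc, TRUE), bc, TRUE),
                 as.numeric(u))
  }
})

test_that("fixed-point encoding respects its error bound", {
  expect_equal(encodeFixedPoint(c(1.001, 2.5), 1000), c(1001, 2500))
  expect_equal(decodeFixedPoint(encodeFixedPoint(c(3, -7), 1), 1), c(3, -7))
  set.seed(1)
  v <- runif(2000, -10, 10)
  err <- abs(decodeFixedPoint(encodeFixedPoint(v, 1000), 1000) - v)
  expect_lte(max(err), 0.5 / 1000)
  expect_error(encodeFixedPoint(1e30, 1000), "fixed-point overflow")
})

test_that("interval quantization hits endpoints and its error bound", {
  q <- encodeIntervalQuantization(c(0, 1), 0, 1, 255)
  expect_equal(q, c(0, 254))
  expect_equal(encodeIntervalQuantization(rep(0.5, 4), 0, 1, 11),
               rep(5, 4))
  expect_error(encodeIntervalQuantization(1, 0, 1, 1), "invalid quantization")
  expect_error(encodeIntervalQuantization(1, 2, 1, 5), "invalid quantization")
  set.seed(2)
  v <- runif(2000, -3, 5)
  for (steps in c(2, 15, 255)) {
    dec <- decodeIntervalQuantization(
      encodeIntervalQuantization(v, -3, 5, steps), -3, 5, steps)
    expect_lte(max(abs(dec - v)), (5 - (-3)) / (2 * (steps - 1)))
  }
})

test_that("string-array encoding builds a shared dictionary", {
  s <- encodeStringArray(c("a", "b", "a"))
  expect_equal(s$stringData, "ab")
  expect_equal(s$offsets, c(0, 1, 2))
  expect_equal(s$indices, c(0, 1, 0))
  allNA <- encodeStringArray(c(NA_character_, NA_character_))
  expect_equal(allNA$indices, c(-1, -1))
  for (seed in 1:20) {
    set.seed(seed)
    v <- sample(c(NA, "alpha", "beta", "g", "delta-5"), 30, replace = TRUE)
    s <- encodeStringArray(v)
    expect_identical(decodeStringArray(s$stringData, s$offsets, s$indices), v)
  }
})

test_that("column chains round-trip losslessly for integers and labels", {
  for (seed in 1:30) {
    set.seed(seed)
    v <- sample(-5e4:5e4, 200, replace = TRUE)
    expect_equal(bcifDecodeColumn(bcifColumn("c", v, "int")), as.numeric(v))
    labs <- rep(sample(0:6, 15, replace = TRUE),
                times = sample(1:30, 15, replace = TRUE))
    expect_equal(bcifDecodeColumn(bcifColumn("l", labs, "labels")),
                 as.numeric(labs))
  }
})

test_that("an RLE-friendly raster encodes smaller than raw int32", {
  raster <- rep(c(0, 3, 0, 2, 0, 1, 0, 4), each = 512)   # 8 runs
  col <- bcifColumn("l", raster, "labels")
  expect_lt(length(col$data$data), 4 * length(raster))
  expect_equal(bcifDecodeColumn(col), raster)
})

test_that("the container serializes and deserializes the logical model", {
  expect_identical(bcifDeserialize(bcifSerialize(list())), list())

  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  blk <- bcifBlock("test", list(bcifCategory("_numbers", list(
    bcifColumn("values", v, "int"),
    bcifColumn("tags", c("x", "y", "x", NA, "z", "x", "y", "z"), "string")),
    length(v))))
  bytes <- bcifSerialize(list(blk))
  back <- bcifDeserialize(bytes)
  expect_length(back, 1L)
  cat1 <- back[[1]]$categories[[1]]
  expect_identical(cat1$name, "_numbers")
  expect_identical(cat1$rowCount, 8)
  expect_equal(bcifDecodeColumn(cat1$columns[[1]]), v)
  expect_identical(bcifDecodeColumn(cat1$columns[[2]]),
                   c("x", "y", "x", NA, "z", "x", "y", "z"))

  expect_error(bcifDeserialize(bytes[1:(length(bytes) - 5)]), "invalid bcif")

  bad <- msgpackEncode(list(encoder = "x", version = "9.9.9",
                            dataBlocks = list()))
  expect_error(bcifDeserialize(bad), "unsupported version")
})

test_that("msgpack round-trips nested structures of every supported type", {
  cases <- list(
    NULL, TRUE, FALSE, 0, 127, 128, 65535, 65536, -1, -32, -33, -129,
    -40000, 2^31 - 1, -2^31, 3.14159, 1e-300, "", "hello",
    strrep("s", 300), as.raw(0:255), list(), setNames(list(), character()),
    list(1, "two", list(3, list(a = 4))),
    list(a = 1, b = list(c = "d", e = as.raw(1:5)), f = NULL)
  )
  for (i in seq_along(cases)) {
    x <- cases[[i]]
    back <- msgpackDecode(msgpackEncode(x))
    expect_equal(back, x, label = sprintf("case %d", i))
  }
  long <- as.list(seq_len(70000))   # forces array32 + int headers
  backLong <- msgpackDecode(msgpackEncode(long))
  expect_equal(unlist(backLong), seq_len(70000))
})
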