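test_that("voxel_volume enforces its invariants", {
  expect_error(voxel_volume(array(0L, c(5, 5, 0)), 9),
               class = "cortexture_format_error")
  expect_error(voxel_volume(array(300L, c(2, 2, 2)), 9),
               class = "cortexture_domain_error")
  expect_error(voxel_volume(array(-1L, c(2, 2, 2)), 9),
               class = "cortexture_domain_error")
  expect_error(voxel_volume(array(0.5, c(2, 2, 2)), 9),
               class = "cortexture_domain_error")
  expect_error(voxel_volume(array(0L, c(2, 2, 2)), 0),
               class = "cortexture_domain_error")
  v <- voxel_volume(array(128L, c(3, 4, 5)), 9)
  expect_identical(dim(v), c(3L, 4L, 5L))
})

test_that("raw binary volumes read back via the JSON sidecar", {
  path <- file.path(withr::local_tempdir(), "vol.raw")
  writeBin(as.raw(rep(0L, 1000)), path)
  jsonlite::write_json(list(nx = 10, ny = 10, nz = 10, voxel_size_um = 9),
                       paste0(path, ".json"), auto_unbox = TRUE)
  v <- read_volume(path)
  expect_identical(v$data, array(0L, c(10, 10, 10)))
  expect_equal(v$voxel_size_um, 9)

  # truncated payload is a format error
  short <- file.path(dirname(path), "short.raw")
  writeBin(as.raw(rep(0L, 999)), short)
  jsonlite::write_json(list(nx = 10, ny = 10, nz = 10, voxel_size_um = 9),
                       paste0(short, ".json"), auto_unbox = TRUE)
  expect_error(read_volume(short), class = "cortexture_format_error")
})

test_that("write_volume / read_volume round-trips bit-identically", {
  dir <- withr::local_tempdir()
  set.seed(11)
  data <- array(sample(0:255, 16 * 12 * 5, replace = TRUE), c(16, 12, 5))
  vol <- voxel_volume(data, voxel_size_um = 9.0)
  path <- file.path(dir, "vol.tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size_um, 9.0)
  expect_error(write_volume(vol, file.path(dir, "nope", "vol.tif")),
               class = "cortexture_io_error")
})

test_that("a directory of slice images reads in lexicographic order", {
  dir <- withr::local_tempdir()
  set.seed(3)
  slices <- lapply(1:56, function(k) {
    matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  })
  for (k in seq_along(slices)) {
    png::writePNG(slices[[k]] / 255,
                  file.path(dir, sprintf("slice_%03d.png", k)))
  }
  jsonlite::write_json(list(voxel_size_um = 9),
                       file.path(dir, "volume.json"), auto_unbox = TRUE)
  v <- read_volume(dir)
  expect_identical(dim(v$data), c(100L, 100L, 56L))
  expect_identical(v$data[, , 1], slices[[1]])
  expect_identical(v$data[, , 56], slices[[56]])
})

test_that("ragged stacks and 16-bit input are rejected", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 10, 10), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 12, 10), file.path(dir, "b.png"))
  expect_error(read_volume(dir, voxel_size_um = 9),
               class = "cortexture_format_error")

  deep <- file.path(dir, "deep.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), deep, bits.per.sample = 16L)
  expect_error(read_volume(deep, voxel_size_um = 9), "16",
               class = "cortexture_depth_error")
})

test_that("write_table renders profile, empty and comparison schemas", {
  dir <- withr::local_tempdir()
  set.seed(5)
  prof <- texture_profile(sample(60:140, 2000, replace = TRUE))
  row <- cbind(data.frame(specimen_id = "s01"), as.data.frame(prof))
  f <- file.path(dir, "profile.csv")
  write_table(row, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_identical(ncol(back), 9L)   # id + 7 parameters + quartile fraction
  expect_equal(back$nakagami, prof$nakagami, tolerance = 1e-12)

  empty <- file.path(dir, "empty.csv")
  write_table(row[0, ], empty)
  expect_identical(length(readLines(empty)), 1L)   # header only

  cmp <- data.frame(parameter = letters[1:7], p_value = runif(7))
  f7 <- file.path(dir, "cmp.csv")
  write_table(cmp, f7)
  expect_identical(nrow(read.csv(f7)), 7L)

  expect_error(write_table(list(list(a = 1), list(b = 2)), f7),
               class = "cortexture_schema_error")
})
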