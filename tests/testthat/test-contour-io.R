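test_that("JSON contour sequences round-trip exactly", {
  sq1 <- rectContour(10, 10)
  sq2 <- rectContour(10, 10, at = c(0, 3))
  seq <- contourSequence("larynx", list(sq1, sq2))
  path <- withr::local_tempfile(fileext = ".json")
  writeContourSequence(seq, path)
  back <- readContourSequence(path)
  expect_identical(roiName(back), "larynx")
  expect_equal(nFrames(back), 2L)
  expect_equal(nPoints(frames(back)[[1L]]), 4L)
  expect_equal(coords(frames(back)[[2L]]), coords(sq2), tolerance = 1e-9)
  expect_equal(pixelSpacing(back), c(1, 1))
  expect_equal(frameInterval(back), 160)
  # write the re-read sequence again: byte-identical files
  path2 <- withr::local_tempfile(fileext = ".json")
  writeContourSequence(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("CSV contour sequences round-trip and respect point order", {
  blob <- blobContour(radius = 7, at = c(10, 10))
  seq <- contourSequence("tongue", list(blob, blob), frameIndices = c(4L, 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeContourSequence(seq, path)
  back <- readContourSequence(path)
  expect_identical(frameIndices(back), c(4L, 7L))
  expect_equal(coords(frames(back)[[1L]]), coords(blob), tolerance = 1e-9)
})

test_that("pixel-unit CSV input is scaled to mm at read time", {
  df <- data.frame(roi = "pc", frame = rep(1:2, each = 3L),
                   point_index = rep(1:3, 2L),
                   x = c(3, 0, 1, 3, 0, 1), y = c(4, 0, 2, 4, 0, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  seq <- readContourSequence(path, pixelSpacing = c(2, 2), units = "pixel")
  expect_equal(coords(frames(seq)[[1L]])[1L, ], c(6, 8))
  # row-flip conversion into the +y-superior frame
  seqf <- readContourSequence(path, pixelSpacing = c(2, 2), units = "pixel",
                              flipRows = 128)
  expect_equal(coords(frames(seqf)[[1L]])[1L, ], c(6, (128 - 1 - 4) * 2))
})

test_that("malformed contour files raise specific errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"roi": "x", "frames": []}', p)   # missing pixel_spacing
  expect_error(readContourSequence(p), "pixel_spacing")
  writeLines('{"roi": "x", "pixel_spacing": [1, 1],
    "frames": [{"index": 1, "points": [[0,0],[1,0]]}]}', p)
  expect_error(readContourSequence(p), "fewer than 3 points")
  writeLines("this is not json", p)
  expect_error(readContourSequence(p), "malformed")
  expect_error(readContourSequence("no/such/file.json"), "not found")
  pc <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", pc)
  expect_error(readContourSequence(pc), "columns")
})

test_that("motion tables round-trip through CSV with the documented shape", {
  pf <- data.frame(frame = 1:20,
                   superior = c(0, abs(rnorm(19))),
                   inferior = c(0, abs(rnorm(19))),
                   anterior = c(0, abs(rnorm(19))),
                   posterior = c(0, abs(rnorm(19))))
  tab <- motionTable("larynx", pf)
  path <- withr::local_tempfile(fileext = ".csv")
  writeMotionTable(tab, path)
  raw <- read.csv(path, colClasses = c(frame = "character"))
  expect_equal(nrow(raw), 20L * 4L + 4L)       # per-frame rows + summary rows
  expect_identical(unique(raw$direction),
                   c("superior", "inferior", "anterior", "posterior"))
  expect_identical(raw$frame[nrow(raw)], "max")
  back <- readMotionTable(path)
  expect_equal(perFrameMotion(back), perFrameMotion(tab), tolerance = 1e-9)
  expect_equal(motionSummary(back), motionSummary(tab), tolerance = 1e-9)
})

test_that("an all-zero single-direction table writes zero summary rows", {
  pf <- data.frame(frame = 1L, superior = 0, inferior = 0, anterior = 0,
                   posterior = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  writeMotionTable(motionTable("hyoid", pf), path)
  raw <- read.csv(path, colClasses = c(frame = "character"))
  expect_equal(nrow(raw), 8L)
  expect_true(all(raw$magnitude_mm == 0))
})

test_that("sequence validity rejects inconsistent metadata", {
  sq <- rectContour()
  expect_error(contourSequence("x", list(sq)), "at least 2")
  expect_error(contourSequence("x", list(sq, sq), pixelSpacing = c(0, 1)),
               "positive")
  expect_error(contourSequence("x", list(sq, sq), frameIndices = c(2L, 2L)),
               "increasing")
  expect_error(contourSequence("", list(sq, sq)), "label")
})
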