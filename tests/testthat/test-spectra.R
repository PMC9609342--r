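test_that("constructor enforces its invariants", {
  expect_error(raman_spectra(c(1, 2, 2), matrix(0, 1, 3)), "increasing")
  expect_error(raman_spectra(1:3, matrix(0, 1, 2)), "channels")
  expect_error(raman_spectra(1:3, matrix(0, 2, 3), c("a", "a")), "duplicate")
  expect_error(raman_spectra(1:3, matrix(c(1, NA, 3), 1, 3)), "non-finite")
  m <- raman_spectra(1:3, matrix(1:6, 2, 3, byrow = TRUE), c("a", "b"))
  expect_equal(dim(m), c(2L, 3L))
})

test_that("wide CSV round-trips exactly", {
  m <- raman_spectra(seq(100, 200, 10), matrix(rnorm(33), 3, 11),
                     c("s1", "s2", "s3"))
  path <- tempfile(fileext = ".csv")
  write_spectra(m, path)
  m2 <- read_spectra(path, "csv")
  expect_equal(m2$axis, m$axis)
  expect_equal(m2$sample_ids, m$sample_ids)
  expect_equal(unname(m2$intensities), unname(m$intensities),
               tolerance = 1e-12)
  unlink(path)
})

test_that("malformed CSVs are rejected with context", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a,a", "100,1,2", "110,3,4"), path)
  expect_error(read_spectra(path, "csv"), "duplicate sample column")
  writeLines(c("wavenumber,a", "110,1", "100,2"), path)
  expect_error(read_spectra(path, "csv"), "strictly increasing")
  writeLines(c("wavenumber,a", "100,1", "110,oops"), path)
  expect_error(read_spectra(path, "csv"), "non-finite")
  unlink(path)
  expect_error(read_spectra("no/such/file.csv", "csv"), "not found")
})

test_that("JCAMP-DX round-trips and reversed axes are re-sorted", {
  m <- raman_spectra(seq(200, 400, 25), matrix(round(rnorm(18), 4), 2, 9),
                     c("u-1", "u-2"))
  dir <- tempfile()
  paths <- write_spectra_jcamp(m, dir)
  m2 <- read_spectra(paths, "jcamp")
  expect_equal(m2$axis, m$axis, tolerance = 1e-8)
  expect_equal(unname(m2$intensities), unname(m$intensities),
               tolerance = 1e-8)
  # hand-written descending-axis file: axis ascends after reading and the
  # intensities follow (oracle = manually sorted copy)
  rev_path <- file.path(dir, "rev.jdx")
  writeLines(c("##TITLE=rev", "##JCAMP-DX=4.24", "##XFACTOR=1",
               "##YFACTOR=1", "##FIRSTX=500", "##LASTX=300", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))",
               "500 10 20 30", "350 40 50", "##END="), rev_path)
  r <- read_spectra(rev_path, "jcamp")
  expect_equal(r$axis, c(300, 350, 400, 450, 500))
  expect_equal(unname(r$intensities[1, ]), c(50, 40, 30, 20, 10))
  unlink(dir, recursive = TRUE)
})

test_that("replicate averaging is a channel-wise mean by group", {
  axis <- 1:4
  X <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1),  # identical
             c(0, 0, 0, 0), c(0, 0, 0, 3), c(0, 0, 0, 0))  # mean 1 at ch 4
  m <- raman_spectra(axis, X, c("a#r1", "a#r2", "a#r3",
                                "b#r1", "b#r2", "b#r3"))
  av <- average_replicates(m)
  expect_equal(av$sample_ids, c("a", "b"))
  expect_equal(unname(av$intensities[1, ]), c(1, 1, 1, 1))
  expect_equal(unname(av$intensities[2, ]), c(0, 0, 0, 1))
  expect_equal(unname(av$meta$replicates), c(3L, 3L))
  # single-replicate groups: identity
  m1 <- raman_spectra(axis, X[c(1, 4), ], c("a", "b"))
  av1 <- average_replicates(m1)
  expect_equal(av1$intensities, m1$intensities)
  # explicit grouping vector, and a malformed key
  avg <- average_replicates(m, rep(c("g1", "g2"), each = 3))
  expect_equal(avg$sample_ids, c("g1", "g2"))
  expect_error(average_replicates(m, c("g1", "g2")), "one label per sample")
})
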