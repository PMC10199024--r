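make_spectra <- function(seed = 1, w = 12, h = 10) {
  set.seed(seed)
  coords <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
  grid <- pixel_grid(w, h, coords, pixel_size = 50)
  n <- nrow(coords)
  mz <- lapply(seq_len(n), function(i) sort(runif(sample(0:6, 1), 100, 600)))
  int <- lapply(mz, function(m) rexp(length(m), 1 / 1000))
  msi_spectra(grid, mz, int)
}

test_that("write/read round-trips every coordinate, m/z and intensity bit-identically", {
  sp <- make_spectra()
  path <- file.path(tempdir(), "phantom12x10.imzML")
  write_imzml(sp, path)
  rt <- read_imzml(path)
  expect_equal(rt$grid$width, 12L)
  expect_equal(rt$grid$height, 10L)
  expect_equal(nrow(rt$grid$coords), 120L)
  expect_identical(rt$grid$coords, sp$grid$coords)
  expect_identical(rt$mz, sp$mz)          # bit-identical doubles
  expect_identical(rt$intensity, sp$intensity)
  # identical content => byte-identical files (UUID derived from payload)
  path2 <- file.path(tempdir(), "phantom_again.imzML")
  write_imzml(sp, path2)
  expect_identical(readBin(sub("imzML$", "ibd", path), "raw", 1e6),
                   readBin(sub("imzML$", "ibd", path2), "raw", 1e6))
})

test_that("a single-pixel single-peak file reads back exactly", {
  grid <- pixel_grid(1, 1, data.frame(x = 0L, y = 0L))
  sp <- msi_spectra(grid, list(255.2330), list(100))
  path <- file.path(tempdir(), "one.imzML")
  write_imzml(sp, path)
  rt <- read_imzml(path)
  expect_identical(rt$mz[[1]], 255.2330)
  expect_identical(rt$intensity[[1]], 100)
})

test_that("a missing .ibd is a fatal error naming the binary", {
  sp <- make_spectra(2, 3, 3)
  path <- file.path(tempdir(), "orphan.imzML")
  write_imzml(sp, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "orphan\\.ibd")
})

test_that("empty-pixel spectra are emitted and read back as empty peak lists", {
  grid <- pixel_grid(2, 1, data.frame(x = 0:1, y = c(0L, 0L)))
  sp <- msi_spectra(grid, list(numeric(0), c(150, 151)), list(numeric(0), c(1, 2)))
  path <- file.path(tempdir(), "empty.imzML")
  write_imzml(sp, path)
  rt <- read_imzml(path)
  expect_length(rt$mz[[1]], 0)
  expect_equal(rt$mz[[2]], c(150, 151))
})

test_that("an independent imzML parser accepts and agrees with our writer", {
  sp <- make_spectra(3, 4, 3)
  path <- file.path(tempdir(), "xcheck.imzML")
  write_imzml(sp, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, it = p.getspectrum(5)",
    "print(json.dumps({'n': len(p.coordinates),",
    "                  'coord5': list(p.coordinates[5])[:2],",
    "                  'mz5': list(mz), 'int5': list(it)}))"), script)
  out <- suppressWarnings(
    system2("python", c(script, path), stdout = TRUE, stderr = FALSE))
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(res$n, 12)
  expect_equal(res$coord5, c(sp$grid$coords$x[6] + 1L, sp$grid$coords$y[6] + 1L))
  expect_equal(res$mz5, sp$mz[[6]])
  expect_equal(res$int5, sp$intensity[[6]])
})
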