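test_that("segmentation recovers the phantom tissue mask at high contrast", {
  ph <- generate_phantom(small_spec(base_intensity = 1e4,
                                    background_intensity = 100, seed = 5))
  mask <- segment_tissue(ph$labeled, seed = 42)
  expect_identical(unclass(mask)[, ], ph$truth$tissue)
})

test_that("segmentation is deterministic under a fixed seed and errors on flat input", {
  ph <- generate_phantom(small_spec(seed = 6))
  m1 <- segment_tissue(ph$labeled, seed = 7)
  m2 <- segment_tissue(ph$labeled, seed = 7)
  expect_identical(m1, m2)

  flat <- ph$labeled
  flat$tensor[] <- 1
  expect_error(segment_tissue(flat), "no variance")
})

test_that("the brighter cluster is labeled tissue", {
  # uniform image plus a block of bright pixels
  palm <- default_targets()[[1]]
  grid <- pixel_grid(6, 6, expand.grid(x = 0:5, y = 0:5))
  ch <- data.frame(target = "palmitate", k = 0:16, mz = palm$mz_ladder)
  tensor <- array(1, dim = c(17, 6, 6))
  tensor[, 2:3, 2:3] <- 500
  st <- ion_image_stack(tensor + array(abs(rnorm(length(tensor), 0, 1e-3)),
                                       dim = dim(tensor)),
                        ch, list(palm), grid)
  mask <- segment_tissue(st, seed = 1)
  expect_true(all(mask[2:3, 2:3]))
  expect_false(any(mask[5:6, 5:6]))
})

test_that("gaussian blur preserves constants, mass, and linearity", {
  const <- matrix(3.7, 9, 7)
  expect_equal(gaussian_denoise(const), const)

  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  out <- gaussian_denoise(imp)
  g <- exp(-(-1:1)^2 / 2); kern <- outer(g, g); kern <- kern / sum(kern)
  expect_equal(out[3, 3], kern[2, 2])
  expect_equal(sum(out), 1, tolerance = 1e-3)  # zero boundary flux

  set.seed(8)
  a <- matrix(runif(35), 7, 5); b <- matrix(runif(35), 7, 5)
  expect_equal(gaussian_denoise(2 * a + 3 * b),
               2 * gaussian_denoise(a) + 3 * gaussian_denoise(b))
})

test_that("tic normalization removes proportional pixel differences", {
  palm <- default_targets()[[1]]
  grid <- pixel_grid(2, 1, data.frame(x = 0:1, y = c(0L, 0L)))
  ch <- data.frame(target = "palmitate", k = 0:16, mz = palm$mz_ladder)
  tensor <- array(0, dim = c(17, 2, 1))
  tensor[1:2, 1, 1] <- c(2, 2)
  tensor[1:2, 2, 1] <- c(4, 4)
  st <- ion_image_stack(tensor, ch, list(palm), grid)
  expect_identical(normalize_pixels(st, "none")$tensor, st$tensor)
  nt <- normalize_pixels(st, "tic")
  expect_equal(nt$tensor[, 1, 1], nt$tensor[, 2, 1])
})

test_that("fractional labeling is invariant to tic normalization", {
  ph <- generate_phantom(small_spec(pool_sdlog = 0.5, seed = 9))
  st <- ph$labeled
  nt <- normalize_pixels(st, "tic")
  A1 <- target_pixel_matrix(st, "palmitate")
  A2 <- target_pixel_matrix(nt, "palmitate")
  keep <- colSums(A1) > 0
  F1 <- sweep(A1[, keep], 2, colSums(A1[, keep]), "/")
  F2 <- sweep(A2[, keep], 2, colSums(A2[, keep]), "/")
  expect_equal(F1, F2, tolerance = 1e-12)
})

test_that("segmentation is invariant to channel order", {
  ph <- generate_phantom(small_spec(seed = 10))
  st <- ph$labeled
  perm <- rev(seq_len(dim(st$tensor)[1]))
  st2 <- st
  st2$tensor <- st$tensor[perm, , ]
  st2$channels <- st$channels[perm, ]
  m1 <- segment_tissue(st, seed = 3)
  m2 <- segment_tissue(st2, seed = 3)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})
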