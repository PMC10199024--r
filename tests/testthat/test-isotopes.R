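test_that("fractional labeling divides by the unmasked isotopologue sum", {
  expect_equal(fractional_labeling(labeling_distribution(c(0, 0, 7))),
               c(0, 0, 1))
  expect_equal(fractional_labeling(labeling_distribution(c(2, 1, 1))),
               c(0.5, 0.25, 0.25))
  # contaminated M1 excluded and the remainder renormalized
  d <- labeling_distribution(c(3, 9, 3, 1), mask = c(TRUE, FALSE, TRUE, TRUE))
  f <- fractional_labeling(d)
  expect_equal(f[c(1, 3, 4)], c(3, 3, 1) / 7)
  expect_true(is.na(f[2]))
  expect_error(fractional_labeling(labeling_distribution(c(0, 0, 0))),
               "undefined")
})

test_that("carbon-atom labeling spans 0 to 1 and is scale-invariant", {
  expect_equal(carbon_atom_labeling(labeling_distribution(c(0, 0, 0, 5))), 1)
  expect_equal(carbon_atom_labeling(labeling_distribution(c(5, 0, 0, 0))), 0)
  expect_equal(carbon_atom_labeling(labeling_distribution(c(0.5, 0, 0.5))), 0.5)
  set.seed(12)
  a <- runif(9)
  expect_equal(carbon_atom_labeling(labeling_distribution(a)),
               carbon_atom_labeling(labeling_distribution(7.3 * a)))
})

test_that("natural-abundance matrix has binomial columns summing to one", {
  expect_equal(na_correction_matrix(5, 0), diag(6))
  p <- 0.0107
  M <- na_correction_matrix(2, p)
  expect_equal(M[, 1], c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_equal(M[, 2], c(0, 1 - p, p))
  expect_equal(M[, 3], c(0, 0, 1))
  set.seed(13)
  for (pp in runif(3)) {
    expect_equal(colSums(na_correction_matrix(7, pp)), rep(1, 8))
  }
})

test_that("NA correction inverts the forward convolution and conserves totals", {
  set.seed(14)
  for (n in c(2, 6, 16, 18)) {
    x_true <- runif(n + 1)
    M <- na_correction_matrix(n)
    a <- as.numeric(M %*% x_true)
    d <- na_correct(labeling_distribution(a, n))
    expect_lt(max(abs(d$a - x_true)) / sum(x_true), 1e-8)
    expect_equal(sum(d$a), sum(a), tolerance = 1e-6)
    expect_true(d$corrected)
  }
})

test_that("an unlabeled natural-abundance pattern corrects to pure M0", {
  a <- stats::dbinom(0:16, 16, 0.0107) * 5e4
  d <- na_correct(labeling_distribution(a, 16))
  expect_gt(fractional_labeling(d)[1], 0.999)
})

test_that("p13 = 0 correction is the identity", {
  set.seed(15)
  a <- runif(7)
  d <- na_correct(labeling_distribution(a, 6), p13 = 0)
  expect_equal(d$a, a, tolerance = 1e-12)
})

test_that("pool-size images honor the isotopologue mask and survive correction", {
  ph <- generate_phantom(noiseless_spec(seed = 16))
  st <- ph$labeled
  full <- pool_size_image(st, "palmitate")
  expect_equal(full[ph$truth$tumor][1],
               ph$spec$base_intensity * ph$spec$pool_scale$tumor)
  m0_only <- pool_size_image(st, "palmitate",
                             mask = c(TRUE, rep(FALSE, 16)))
  expect_equal(m0_only, st$tensor[1, , ])
  corr <- na_correct_stack(st)
  expect_equal(pool_size_image(corr, "palmitate"), full, tolerance = 1e-6)
})

test_that("injected contaminants at palmitate M1/M4/M5 are flagged exactly", {
  sp <- small_spec(contaminants = palmitate_contaminants(intensity = 2000),
                   seed = 17)
  ph <- generate_phantom(sp)
  rep <- screen_interferences(ph$unlabeled, ph$unlabeled$targets,
                              threshold = 0.02, tissue_mask = ph$truth$tissue)
  flagged <- rep[rep$flagged, ]
  expect_setequal(paste(flagged$target, flagged$k),
                  c("palmitate 1", "palmitate 4", "palmitate 5"))
  expect_equal(attr(rep, "status"), "screened")
  msk <- interference_mask(rep, "palmitate")
  expect_equal(which(!msk), c(2, 5, 6))
})

test_that("a clean unlabeled phantom produces no flags and M0 is never flagged", {
  ph <- generate_phantom(small_spec(seed = 18))
  rep <- screen_interferences(ph$unlabeled, ph$unlabeled$targets,
                              tissue_mask = ph$truth$tissue)
  expect_false(any(rep$flagged))
  # threshold 1 flags nothing even with gross contamination
  ph2 <- generate_phantom(small_spec(
    contaminants = palmitate_contaminants(1e5), seed = 19))
  rep2 <- screen_interferences(ph2$unlabeled, ph2$unlabeled$targets,
                               threshold = 1, tissue_mask = ph2$truth$tissue)
  expect_false(any(rep2$flagged))
})

test_that("a labeled stack or no control is rejected/reported properly", {
  ph <- generate_phantom(small_spec(seed = 20))
  expect_error(screen_interferences(ph$labeled, ph$labeled$targets),
               "unlabeled")
  rep <- screen_interferences(NULL, ph$labeled$targets)
  expect_equal(attr(rep, "status"), "unscreened")
  expect_false(any(rep$flagged))
})

test_that("fractional labeling is invariant to per-pixel multiplicative matrix effects", {
  ph <- generate_phantom(small_spec(seed = 21))
  st <- ph$labeled
  set.seed(22)
  # power-of-two scalar field: exact mantissa preservation, so fractions are
  # bitwise identical while pool sizes change
  field <- matrix(2^sample(-3:3, st$grid$width * st$grid$height, TRUE),
                  st$grid$width, st$grid$height)
  st2 <- st
  for (ch in seq_len(dim(st$tensor)[1])) {
    st2$tensor[ch, , ] <- st$tensor[ch, , ] * field
  }
  A1 <- target_pixel_matrix(st, "palmitate")
  A2 <- target_pixel_matrix(st2, "palmitate")
  keep <- colSums(A1) > 0
  F1 <- sweep(A1[, keep], 2, colSums(A1[, keep]), "/")
  F2 <- sweep(A2[, keep], 2, colSums(A2[, keep]), "/")
  expect_identical(F1, F2)
  expect_false(isTRUE(all.equal(pool_size_image(st, "palmitate"),
                                pool_size_image(st2, "palmitate"))))
})
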