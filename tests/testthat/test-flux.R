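test_that("a noiseless uniform phantom yields a uniform flux map", {
  sp <- noiseless_spec(g = list(tumor = c(palmitate = 0.3, stearate = 0.1),
                                healthy = c(palmitate = 0.3, stearate = 0.1)),
                       e = list(tumor = c(stearate = 0.1),
                                healthy = c(stearate = 0.1)),
                       X = list(tumor = c(0.4, 0.2, 0.4),
                                healthy = c(0.4, 0.2, 0.4)),
                       seed = 30)
  ph <- generate_phantom(sp)
  corr <- na_correct_stack(ph$labeled, tissue_mask = ph$truth$tissue)
  fx <- flux_image(corr, "palmitate", tissue_mask = ph$truth$tissue)
  gv <- fx$g[ph$truth$tissue]
  expect_true(all(abs(gv - 0.3) < 1e-3))
  expect_equal(fx$n_failed, 0L)
})

test_that("flux model and target requirements are validated", {
  ph <- generate_phantom(noiseless_spec(seed = 31))
  corr <- na_correct_stack(ph$labeled, tissue_mask = ph$truth$tissue)
  expect_error(flux_image(corr, "palmitate", model = "elongation"),
               "19-isotopologue")
})

test_that("region summaries report means, SDs, ratio and reject bad ROIs", {
  ph <- generate_phantom(small_spec(seed = 32))
  corr <- na_correct_stack(ph$labeled, tissue_mask = ph$truth$tissue)
  fx <- flux_image(corr, "palmitate", tissue_mask = ph$truth$tissue)
  rs <- region_summary(fx, ph$truth$tumor, ph$truth$healthy)
  expect_equal(rs$mean_a, 0.55, tolerance = 0.02)
  expect_equal(rs$mean_b, 0.20, tolerance = 0.02)
  expect_gt(rs$ratio, 2)
  expect_error(region_summary(fx, ph$truth$tumor, ph$truth$tumor), "disjoint")
  empty <- matrix(FALSE, nrow(fx$g), ncol(fx$g))
  expect_error(region_summary(fx, empty, ph$truth$healthy), "empty ROI")

  # single-pixel ROIs: mean is the pixel value, SD is NA -> reported as is
  one_a <- empty; one_b <- empty
  idx <- which(ph$truth$tumor & !is.na(fx$g), arr.ind = TRUE)
  one_a[idx[1, 1], idx[1, 2]] <- TRUE
  one_b[idx[2, 1], idx[2, 2]] <- TRUE
  rs1 <- region_summary(fx, one_a, one_b)
  expect_equal(rs1$mean_a, fx$g[idx[1, 1], idx[1, 2]])
  expect_equal(rs1$n_a, 1L)
})

test_that("replicate flux images are compared with a paired t test", {
  imgs <- lapply(c(33, 34, 35), function(s) {
    ph <- generate_phantom(small_spec(seed = s))
    corr <- na_correct_stack(ph$labeled, tissue_mask = ph$truth$tissue)
    flux_image(corr, "palmitate", tissue_mask = ph$truth$tissue)
  })
  ph <- generate_phantom(small_spec(seed = 33))
  rs <- region_summary(imgs, ph$truth$tumor, ph$truth$healthy)
  expect_equal(rs$n_replicates, 3L)
  expect_equal(rs$mean_a, 0.55, tolerance = 0.02)
  expect_lt(rs$p, 0.05)
})

test_that("flux tables and plots expose fitted pixels", {
  ph <- generate_phantom(small_spec(seed = 36))
  corr <- na_correct_stack(ph$labeled, tissue_mask = ph$truth$tissue)
  fx <- flux_image(corr, "palmitate", tissue_mask = ph$truth$tissue,
                   t_hours = 48)
  tab <- flux_table(fx)
  expect_equal(nrow(tab), fx$n_fitted)
  expect_true(all(tab$g >= 0 & tab$g <= 1))
  pdf(NULL)
  expect_silent(plot(fx))
  dev.off()
  expect_output(print(fx), "48")
})
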