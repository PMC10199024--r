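test_that("unlabeled noiseless tissue has near-zero measured labeling error", {
  ph <- generate_phantom(noiseless_spec(seed = 40))
  err <- measure_labeling_error(ph$unlabeled, "palmitate",
                                tissue_mask = ph$truth$tissue)
  expect_lt(err, 1e-10)
})

test_that("measured error matches the noise-model expectation under known noise", {
  # additive fractional Gaussian noise SD 0.01 on a large unlabeled phantom.
  # Without clipping each isotopologue's |deviation| would have the
  # folded-normal mean sigma * sqrt(2/pi) ~ 0.00798; clipping at zero and
  # renormalizing shrinks deviations on the many near-zero isotopologues.
  # 0.006684 is the Monte-Carlo expectation of mean |f - theo| for the
  # palmitate natural-abundance pattern under this exact noise model
  # (200k draws, independent of the imaging pipeline).
  ph <- generate_phantom(phantom_spec(noise_rel = 0, noise_frac = 0.01,
                                      background_intensity = 0, seed = 41))
  err <- measure_labeling_error(ph$unlabeled, "palmitate",
                                tissue_mask = ph$truth$tissue)
  expect_gt(sum(ph$truth$tissue), 1000)
  expect_lt(abs(err - 0.006684) / 0.006684, 0.1)
  expect_lt(err, 0.01 * sqrt(2 / pi))   # folded-normal ceiling
  expect_gt(err, 0.01 / sqrt(2 * pi))   # half-normal floor
})

test_that("measured error is invariant to per-pixel intensity scaling", {
  ph <- generate_phantom(small_spec(pool_sdlog = 0.8, seed = 42))
  st <- ph$unlabeled
  e1 <- measure_labeling_error(st, "palmitate", tissue_mask = ph$truth$tissue)
  for (ch in seq_len(dim(st$tensor)[1])) st$tensor[ch, , ] <- st$tensor[ch, , ] * 4
  e2 <- measure_labeling_error(st, "palmitate", tissue_mask = ph$truth$tissue)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("flux error grows with injected noise and is reproducible", {
  res1 <- noise_gradient_simulation("sisa", sigma_levels = c(0.004, 0.04),
                                    n_reps = 40, seed = 43)
  res2 <- noise_gradient_simulation("sisa", sigma_levels = c(0.004, 0.04),
                                    n_reps = 40, seed = 43)
  expect_identical(res1$draws, res2$draws)
  expect_lt(res1$levels$g_err[1], res1$levels$g_err[2])
  expect_gt(res1$slope, 0)
  # near-noiseless level recovers cleanly
  res0 <- noise_gradient_simulation("sisa", sigma_levels = c(1e-6, 1e-3),
                                    n_reps = 15, seed = 44)
  expect_lt(res0$levels$g_err[1], 1e-3)
})

test_that("elongation noise gradient reports e errors too", {
  res <- noise_gradient_simulation("elongation",
                                   sigma_levels = c(0.003, 0.03),
                                   n_reps = 15, seed = 45)
  expect_true(all(is.finite(res$levels$e_err)))
  expect_lt(res$levels$g_err[1], res$levels$g_err[2])
})

test_that("error projection interpolates the regression and flags extrapolation", {
  res <- noise_gradient_simulation("sisa",
                                   sigma_levels = c(0.005, 0.01, 0.02, 0.04),
                                   n_reps = 50, seed = 46)
  # projecting at a simulated level lands within that level's spread
  lvl <- 3
  pr <- project_error(res, res$sigma_levels[lvl])
  expect_lt(abs(pr$mean - res$levels$g_err[lvl]),
            2 * res$levels$g_err_sd[lvl] + 1e-3)
  # at zero, the projection is the intercept
  pr0 <- suppressWarnings(project_error(res, 0))
  expect_equal(pr0$mean, res$intercept)
  expect_warning(project_error(res, 0.5), "extrapolat")
  # linearity: doubling all errors doubles slope and centered projection
  res2 <- res
  res2$levels$g_err <- 2 * res$levels$g_err
  reg2 <- stats::lm(g_err ~ sigma, data = res2$levels)
  res2$slope <- unname(coef(reg2)[2]); res2$intercept <- unname(coef(reg2)[1])
  pr2 <- project_error(res2, res$sigma_levels[lvl])
  expect_equal(pr2$mean - res2$intercept, 2 * (pr$mean - res$intercept),
               tolerance = 1e-10)
})

test_that("projected error brackets observed error on an independent phantom", {
  sigma <- 0.01
  res <- noise_gradient_simulation("sisa",
                                   sigma_levels = c(0.004, 0.008, 0.016, 0.032),
                                   n_reps = 60, seed = 47)
  pr <- project_error(res, sigma)
  # independent draws at the measured noise level
  set.seed(48)
  errs <- replicate(40, {
    X <- random_simplex(); g <- runif(1)
    p <- sisa_forward(X, c(1, 0, 0), g, 8)
    f <- pmax(p + rnorm(17, 0, sigma), 0); f <- f / sum(f)
    abs(fit_sisa(f, N = c(1, 0, 0), n_subunits = 8)$g - g)
  })
  expect_lt(abs(mean(errs) - pr$mean), 2 * pr$sd)
})
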