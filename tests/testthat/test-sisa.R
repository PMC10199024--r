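N0 <- c(1, 0, 0)

test_that("monomer_power matches exhaustive enumeration and boundary cases", {
  expect_equal(monomer_power(c(1, 0, 0), 8), c(1, rep(0, 16)))
  expect_equal(monomer_power(c(0, 0, 1), 8), c(rep(0, 16), 1))
  m <- c(0.5, 0.3, 0.2)
  expect_equal(monomer_power(m, 3), enumerate_monomers(m, 3), tolerance = 1e-12)
  set.seed(23)
  m2 <- random_simplex()
  expect_equal(monomer_power(m2, 4), enumerate_monomers(m2, 4),
               tolerance = 1e-12)
})

test_that("forward models conserve total fraction and satisfy boundary cases", {
  prec <- precursor_distribution(N = N0, T = c(0.1, 0.2, 0.7), D = 0.6)
  expect_equal(isa_forward(prec, 0, 8), monomer_power(N0, 8))
  p <- isa_forward(precursor_distribution(N = N0, T = c(0, 0, 1), D = 1), 1, 8)
  expect_equal(p[17], 1)
  expect_equal(sisa_forward(c(0.2, 0.3, 0.5), N0, 0, 8), monomer_power(N0, 8))
  expect_length(sisa_forward(c(0.2, 0.3, 0.5), N0, 0.4, 8), 17)
  expect_equal(elongation_forward(c(0.2, 0.3, 0.5), N0, 0, 0),
               monomer_power(N0, 9))
  set.seed(24)
  for (i in 1:20) {
    X <- random_simplex(); Tv <- random_simplex()
    g <- runif(1); D <- runif(1); e <- runif(1, 0, 1 - g)
    expect_equal(sum(sisa_forward(X, N0, g, 8)), 1, tolerance = 1e-12)
    expect_equal(sum(isa_forward(precursor_distribution(N0, Tv, D), g, 8)), 1,
                 tolerance = 1e-12)
    expect_equal(sum(elongation_forward(X, N0, g, e)), 1, tolerance = 1e-12)
  }
})

test_that("SISA with X = (1-D)N + DT reproduces classical ISA exactly", {
  set.seed(25)
  for (i in 1:20) {
    Tv <- random_simplex(); D <- runif(1); g <- runif(1)
    N <- natural_monomer()
    p1 <- isa_forward(precursor_distribution(N, Tv, D), g, 8)
    p2 <- sisa_forward((1 - D) * N + D * Tv, N, g, 8)
    expect_equal(p1, p2, tolerance = 1e-15)
  }
})

test_that("pure elongation of unlabeled palmitate yields M2 stearate", {
  e <- 0.25
  p <- elongation_forward(c(0, 0, 1), N0, 0, e)
  expect_equal(p[3], e)      # M2
  expect_equal(p[1], 1 - e)  # M0
  expect_equal(sum(p[-c(1, 3)]), 0)
})

test_that("noiseless SISA fits recover the generating parameters", {
  obs <- sisa_forward(c(0.4, 0.2, 0.4), N0, 0.5, 8)
  fit <- fit_sisa(obs, N = N0, n_subunits = 8)
  expect_lt(abs(fit$g - 0.5), 1e-4)
  expect_lt(max(abs(fit$X - c(0.4, 0.2, 0.4))), 1e-3)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["g"]), fit$g)

  # no synthesis
  fit0 <- fit_sisa(monomer_power(N0, 8), N = N0, n_subunits = 8)
  expect_lt(abs(fit0$g), 1e-4)
})

test_that("the fit matches a dense grid-search oracle", {
  obs <- sisa_forward(c(0.3, 0.45, 0.25), N0, 0.62, 8)
  fit <- fit_sisa(obs, N = N0, n_subunits = 8)
  # oracle: profile g in closed form over a dense simplex grid of X
  C <- monomer_power(N0, 8)
  best <- list(sse = Inf)
  for (x0 in seq(0, 1, 0.05)) for (x1 in seq(0, 1 - x0, 0.05)) {
    X <- c(x0, x1, 1 - x0 - x1)
    A <- monomer_power(X, 8)
    d <- A - C
    if (sum(d * d) < 1e-30) next
    g <- min(1, max(0, sum((obs - C) * d) / sum(d * d)))
    sse <- sum((C + g * (A - C) - obs)^2)
    if (sse < best$sse) best <- list(sse = sse, X = X, g = g)
  }
  expect_lte(fit$sse, best$sse + 1e-12)
  expect_lt(max(abs(fit$X - c(0.3, 0.45, 0.25))), 0.05)
  expect_lt(abs(best$g - 0.62), 0.05)
})

test_that("masked fits (DESI palmitate exclusions) still recover parameters", {
  mask <- rep(TRUE, 17); mask[c(2, 5, 6)] <- FALSE
  obs <- sisa_forward(c(0.45, 0.15, 0.40), N0, 0.35, 8)
  fit <- fit_sisa(obs, N = N0, n_subunits = 8, mask = mask)
  expect_lt(abs(fit$g - 0.35), 1e-2)
  expect_lt(max(abs(fit$X - c(0.45, 0.15, 0.40))), 1e-2)
  expect_equal(fit$n_unmasked, 14L)
})

test_that("noiseless elongation fits recover both flux fractions", {
  obs <- elongation_forward(c(0.5, 0.1, 0.4), N0, 0.3, 0.2)
  fit <- fit_elongation(obs, N = N0)
  expect_lt(abs(fit$g - 0.3), 1e-3)
  expect_lt(abs(fit$e - 0.2), 1e-3)
  fit0 <- fit_elongation(monomer_power(N0, 9), N = N0)
  expect_lt(abs(fit0$g), 1e-3)
  expect_lt(abs(fit0$e), 1e-3)
})

test_that("the elongation term is needed: nested-model sse inequality", {
  set.seed(26)
  obs <- elongation_forward(c(0.5, 0.1, 0.4), N0, 0.3, 0.2)
  obs <- pmax(obs + rnorm(19, 0, 0.005), 0); obs <- obs / sum(obs)
  full <- fit_elongation(obs, N = N0)
  g_only <- fit_sisa(obs, N = N0, n_subunits = 9)
  expect_lt(full$sse, g_only$sse)
})

test_that("underdetermined and invalid inputs are rejected", {
  obs <- sisa_forward(c(0.4, 0.2, 0.4), N0, 0.5, 8)
  mask <- rep(FALSE, 17); mask[1:4] <- TRUE
  expect_error(fit_sisa(obs, N = N0, n_subunits = 8, mask = mask),
               "underdetermined")
  obs_bad <- obs; obs_bad[3] <- NaN
  expect_error(fit_sisa(obs_bad, N = N0, n_subunits = 8), "non-finite")
  expect_error(fit_elongation(obs, N = N0), "length")
})

test_that("sisa_fit methods are coherent: predict, residuals, simulate", {
  obs <- sisa_forward(c(0.4, 0.2, 0.4), N0, 0.5, 8)
  fit <- fit_sisa(obs, N = N0, n_subunits = 8)
  expect_equal(predict(fit), obs, tolerance = 1e-5)
  expect_lt(max(abs(residuals(fit)), na.rm = TRUE), 1e-6)
  s1 <- simulate(fit, nsim = 3, seed = 101, sigma = 0.01)
  s2 <- simulate(fit, nsim = 3, seed = 101, sigma = 0.01)
  expect_identical(s1, s2)
  expect_equal(rowSums(s1), rep(1, 3))
  expect_output(print(summary(fit)), "RMSE")
})
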