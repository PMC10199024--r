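# Isotopologue spectral analysis: forward models for polymer labeling as a
# polynomial in monomer (acetyl-CoA) labeling, and per-pixel fitting.
#
# Classical ISA writes the product distribution as
#   P = g * conv^n((1-D) N + D T) + (1-g) * conv^n(N)
# with known tracer labeling T and dilution D. SISA replaces the tracer terms
# with a single inferred monomer distribution X:
#   P = g * conv^n(X) + (1-g) * conv^n(N)
# and the elongation model splits stearate synthesis into full de novo
# synthesis (9 subunits from X) and elongation of pre-existing palmitate:
#   P = g * conv^9(X) + e * X (*) conv^8(N) + (1-g-e) * conv^9(N).
#
# Because every model is linear in the flux fractions (g, or g and e), those
# are profiled out in closed form (least squares constrained to the unit
# interval / triangle) and numerical optimization runs only over the monomer
# labeling X on the simplex.

.check_simplex <- function(m, name = "m", tol = 1e-9) {
  if (length(m) != 3L || any(m < -tol) || abs(sum(m) - 1) > tol) {
    stop(name, " must be a 3-vector on the probability simplex")
  }
  pmax(m, 0) / sum(pmax(m, 0))
}

#' Mass distribution of k independent monomers
#'
#' k-fold self-convolution of a monomer labeling 3-vector `(m0, m1, m2)`:
#' the isotopologue distribution of a polymer built from `k` independent
#' draws of that monomer. Output has length `2k + 1` and sums to 1.
#'
#' @param m monomer mass distribution, 3-vector on the simplex.
#' @param k number of subunits (>= 1).
#' @return Numeric vector `P_0..P_2k`.
#' @export
monomer_power <- function(m, k) {
  stopifnot(k >= 1)
  m <- .check_simplex(m)
  .mp_fast(m, k)
}

# unchecked k-fold self-convolution (hot path of the per-pixel fits)
.mp_fast <- function(m, k) {
  out <- m
  if (k > 1) for (i in 2:k) {
    L <- length(out)
    new <- numeric(L + 2L)
    new[1:L] <- m[1] * out
    new[2:(L + 1L)] <- new[2:(L + 1L)] + m[2] * out
    new[3:(L + 2L)] <- new[3:(L + 2L)] + m[3] * out
    out <- new
  }
  out
}

# open convolution of two mass distributions
.conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Precursor labeling description for classical ISA
#'
#' @param N natural/pre-existing monomer labeling, simplex 3-vector.
#' @param T tracer-derived monomer labeling, simplex 3-vector.
#' @param D fraction of the monomer pool drawn from the tracer, in `[0, 1]`.
#' @param X inferred monomer labeling (SISA), simplex 3-vector or `NULL`.
#' @return A `precursor_distribution` list.
#' @export
precursor_distribution <- function(N = c(1, 0, 0), T = NULL, D = NULL,
                                   X = NULL) {
  N <- .check_simplex(N, "N")
  if (!is.null(T)) T <- .check_simplex(T, "T")
  if (!is.null(D)) stopifnot(D >= 0, D <= 1)
  if (!is.null(X)) X <- .check_simplex(X, "X")
  structure(list(N = N, T = T, D = D, X = X),
            class = "precursor_distribution")
}

#' Classical ISA forward model
#'
#' Predicted isotopologue fractions of a polymer with `n_subunits` monomer
#' subunits, given tracer labeling `T`, dilution `D`, pre-existing labeling
#' `N` and fractional turnover `g`.
#'
#' @param prec a [precursor_distribution()] with `N`, `T`, `D` set.
#' @param g fractional turnover in `[0, 1]`.
#' @param n_subunits number of monomer subunits (8 for palmitate).
#' @return Fractions `P_0..P_{2 n_subunits}`, summing to 1.
#' @export
isa_forward <- function(prec, g, n_subunits) {
  stopifnot(g >= 0, g <= 1, !is.null(prec$T), !is.null(prec$D))
  mix <- (1 - prec$D) * prec$N + prec$D * prec$T
  g * monomer_power(mix, n_subunits) +
    (1 - g) * monomer_power(prec$N, n_subunits)
}

#' SISA forward model
#'
#' As [isa_forward()] but with the new-synthesis monomer labeling given
#' directly as `X`; setting `X = (1-D) N + D T` reproduces classical ISA
#' exactly.
#'
#' @param X inferred monomer labeling, simplex 3-vector.
#' @param N pre-existing monomer labeling, simplex 3-vector.
#' @param g fractional turnover in `[0, 1]`.
#' @param n_subunits number of monomer subunits.
#' @return Fractions `P_0..P_{2 n_subunits}`.
#' @export
sisa_forward <- function(X, N, g, n_subunits) {
  stopifnot(g >= 0, g <= 1)
  g * monomer_power(X, n_subunits) + (1 - g) * monomer_power(N, n_subunits)
}

#' Elongation forward model (stearate)
#'
#' Splits newly made stearate into full de novo synthesis (9 labeled-pool
#' subunits, fraction `g`) and elongation of pre-existing palmitate by one
#' labeled-pool acetyl unit (fraction `e`); the remainder `1 - g - e` is
#' pre-existing stearate. With unlabeled `N` and fully labeled monomers,
#' elongation alone produces M2 stearate.
#'
#' @inheritParams sisa_forward
#' @param e elongation fraction; `g + e <= 1`.
#' @return Fractions `P_0..P_18`.
#' @export
elongation_forward <- function(X, N, g, e) {
  stopifnot(g >= 0, e >= 0, g + e <= 1 + 1e-12)
  X <- .check_simplex(X, "X"); N <- .check_simplex(N, "N")
  g * monomer_power(X, 9) +
    e * .conv(X, monomer_power(N, 8)) +
    (1 - g - e) * monomer_power(N, 9)
}

# ---- fitting ----------------------------------------------------------------

# Constrained 1-D least squares: min_{0<=t<=1} ||C + t*(A - C) - f||^2
.profile_line <- function(A, C, f) {
  d <- A - C
  dd <- sum(d * d)
  if (dd < 1e-30) return(0)
  min(1, max(0, sum((f - C) * d) / dd))
}

# Constrained 2-D least squares over the triangle a,b >= 0, a + b <= 1:
# min || C + a*(A - C) + b*(B - C) - f ||^2
.profile_triangle <- function(A, B, C, f) {
  u <- A - C; v <- B - C; r <- f - C
  G <- matrix(c(sum(u * u), sum(u * v), sum(u * v), sum(v * v)), 2, 2)
  h <- c(sum(u * r), sum(v * r))
  sol <- tryCatch(solve(G, h), error = function(e) NULL)
  feasible <- function(ab) ab[1] >= 0 && ab[2] >= 0 && sum(ab) <= 1
  if (!is.null(sol) && feasible(sol)) return(sol)
  # project onto each edge of the triangle, keep the best
  cand <- list(
    c(.profile_line(A, C, f), 0),                       # edge b = 0
    c(0, .profile_line(B, C, f)),                       # edge a = 0
    { t <- .profile_line(B, A, f); c(1 - t, t) }        # edge a + b = 1
  )
  sse <- vapply(cand, function(ab) {
    sum((C + ab[1] * u + ab[2] * v - f)^2)
  }, 0)
  cand[[which.min(sse)]]
}

# squared-then-normalized simplex parameterization
.to_simplex <- function(u) { s <- u * u; s / sum(s) }

# default multi-start X values (two seeded random simplex points appended)
.x_starts <- function(N, n_random = 2, seed = 171) {
  starts <- list(
    0.9 * N + 0.1 * rep(1 / 3, 3),
    rep(1 / 3, 3),
    c(0.2, 0.2, 0.6),
    c(0.6, 0.2, 0.2)
  )
  if (n_random > 0) {
    rnd <- .with_seed(seed, {
      lapply(seq_len(n_random), function(i) {
        v <- stats::rexp(3); v / sum(v)
      })
    })
    starts <- c(starts, rnd)
  }
  starts
}

# Shared fitting engine. basis(X) must return a list of mass-distribution
# vectors: list(A) for sisa (flux params (g)), list(A, B) for elongation
# (flux params (g, e)); C is the pre-existing-pool distribution.
.fit_engine <- function(f_obs, mask, N, C, basis, n_par_flux,
                        starts, reltol = 1e-12) {
  un <- which(mask & !is.na(f_obs))
  f_sub <- f_obs[un]
  f_sub <- f_sub / sum(f_sub)
  C_u <- C[un]; sC <- sum(C_u)

  Ct <- if (sC > 1e-300) C_u / sC else C_u * 0

  eval_at <- function(X) {
    bs <- basis(X)
    if (n_par_flux == 1L) {
      A_u <- bs[[1]][un]
      sA <- sum(A_u)
      At <- if (sA > 1e-300) A_u / sA else A_u * 0
      gam <- .profile_line(At, Ct, f_sub)
      pred <- Ct + gam * (At - Ct)
      list(sse = sum((pred - f_sub)^2), gam = gam, ss = sA, pred = pred)
    } else {
      A_u <- bs[[1]][un]; B_u <- bs[[2]][un]
      sA <- sum(A_u); sB <- sum(B_u)
      At <- if (sA > 1e-300) A_u / sA else A_u * 0
      Bt <- if (sB > 1e-300) B_u / sB else B_u * 0
      ab <- .profile_triangle(At, Bt, Ct, f_sub)
      pred <- Ct + ab[1] * (At - Ct) + ab[2] * (Bt - Ct)
      list(sse = sum((pred - f_sub)^2), gam = ab, ss = c(sA, sB), pred = pred)
    }
  }
  obj <- function(u) { s <- u * u; eval_at(s / sum(s))$sse }

  best <- NULL
  converged <- FALSE
  for (x0 in starts) {
    u0 <- sqrt(pmax(x0, 1e-6))
    fit <- tryCatch({
      nm <- stats::optim(u0, obj, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = 2000))
      stats::optim(nm$par, obj, method = "BFGS",
                   control = list(reltol = reltol, maxit = 500))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(X = rep(NA_real_, 3), gam = rep(NA_real_, n_par_flux),
                sse = NA_real_, converged = FALSE, ss = NULL,
                n_unmasked = length(un)))
  }
  X <- .to_simplex(best$par)
  ev <- eval_at(X)
  list(X = X, gam = ev$gam, sse = ev$sse, converged = converged,
       ss = ev$ss, sC = sC, n_unmasked = length(un), pred_sub = ev$pred,
       unmasked = un, f_sub = f_sub)
}

#' Fit the SISA model to one isotopologue distribution
#'
#' Jointly infers the monomer labeling `X` and fractional turnover `g` by
#' minimizing the sum of squared differences between observed and predicted
#' isotopologue fractions over the unmasked isotopologues. Both observation
#' and prediction are renormalized over the unmasked set, so excluded
#' (interference-flagged) isotopologues do not bias the fit. `g` is profiled
#' out in closed form; optimization runs over `X` on the simplex with
#' multiple starts.
#'
#' @param observed isotopologue fractions `f_0..f_2n` (a numeric vector or a
#'   corrected [labeling_distribution()]); masked entries may be `NA`.
#' @param N pre-existing-pool monomer labeling. Default `c(1, 0, 0)` assumes
#'   NA-corrected input; use `natural_monomer(p13)` for uncorrected data.
#' @param n_subunits number of monomer subunits (8 for palmitate).
#' @param mask logical usability vector over `P_0..P_2n` (default from the
#'   `labeling_distribution`, else all TRUE); at least 5 unmasked entries are
#'   required (4 free parameters).
#' @param starts list of starting `X` simplex vectors; default
#'   [.x_starts()]-style multistart.
#' @param reltol optimizer relative tolerance on the objective.
#' @return A `sisa_fit` object: fields `g`, `e` (`NA` here), `X`, `sse`,
#'   `converged`, `n_unmasked`, plus the data needed by `predict`/`residuals`.
#' @export
fit_sisa <- function(observed, N = c(1, 0, 0), n_subunits,
                     mask = NULL, starts = NULL, reltol = 1e-12) {
  if (inherits(observed, "labeling_distribution")) {
    if (is.null(mask)) mask <- observed$mask
    observed <- fractional_labeling(observed)
  }
  len <- 2L * n_subunits + 1L
  stopifnot(length(observed) == len)
  if (is.null(mask)) mask <- rep(TRUE, len)
  if (sum(mask & !is.na(observed)) < 5L) {
    stop("underdetermined: need >= 5 unmasked isotopologue fractions")
  }
  if (any(!is.finite(observed[mask]))) stop("non-finite observed fractions")
  N <- .check_simplex(N, "N")
  if (is.null(starts)) starts <- .x_starts(N)
  C <- monomer_power(N, n_subunits)
  eng <- .fit_engine(observed, mask, N, C,
                     basis = function(X) list(.mp_fast(X, n_subunits)),
                     n_par_flux = 1L, starts = starts, reltol = reltol)
  g <- if (eng$converged) {
    gam <- eng$gam
    sA <- eng$ss[1]
    gam * eng$sC / ((1 - gam) * sA + gam * eng$sC)
  } else NA_real_
  structure(list(g = g, e = NA_real_, X = eng$X, N = N, sse = eng$sse,
                 converged = eng$converged, n_unmasked = eng$n_unmasked,
                 model = "sisa", n_subunits = n_subunits,
                 observed = observed, mask = mask),
            class = "sisa_fit")
}

#' Fit the elongation model (stearate) to one isotopologue distribution
#'
#' As [fit_sisa()] but over 19 isotopologues with both the de novo fraction
#' `g` and elongation fraction `e` inferred, constrained to `g, e >= 0`,
#' `g + e <= 1` (handled exactly by the profiled constrained least squares).
#'
#' @inheritParams fit_sisa
#' @param observed fractions `f_0..f_18`; at least 6 unmasked entries.
#' @return A `sisa_fit` with `e` set and `model = "elongation"`.
#' @export
fit_elongation <- function(observed, N = c(1, 0, 0), mask = NULL,
                           starts = NULL, reltol = 1e-12) {
  if (inherits(observed, "labeling_distribution")) {
    if (is.null(mask)) mask <- observed$mask
    observed <- fractional_labeling(observed)
  }
  stopifnot(length(observed) == 19L)
  if (is.null(mask)) mask <- rep(TRUE, 19L)
  if (sum(mask & !is.na(observed)) < 6L) {
    stop("underdetermined: need >= 6 unmasked isotopologue fractions")
  }
  if (any(!is.finite(observed[mask]))) stop("non-finite observed fractions")
  N <- .check_simplex(N, "N")
  if (is.null(starts)) starts <- .x_starts(N)
  C <- monomer_power(N, 9)
  B_of <- local({
    mpN8 <- monomer_power(N, 8)
    function(X) list(.mp_fast(X, 9), .conv(X, mpN8))
  })
  eng <- .fit_engine(observed, mask, N, C, basis = B_of,
                     n_par_flux = 2L, starts = starts, reltol = reltol)
  if (eng$converged) {
    ab <- eng$gam; sA <- eng$ss[1]; sB <- eng$ss[2]; sC <- eng$sC
    S <- 1 / (ab[1] / sA + ab[2] / sB + (1 - sum(ab)) / sC)
    g <- ab[1] * S / sA
    e <- ab[2] * S / sB
  } else g <- e <- NA_real_
  structure(list(g = g, e = e, X = eng$X, N = N, sse = eng$sse,
                 converged = eng$converged, n_unmasked = eng$n_unmasked,
                 model = "elongation", n_subunits = 9L,
                 observed = observed, mask = mask),
            class = "sisa_fit")
}

#' Monomer labeling at natural abundance
#'
#' The 2-carbon acetyl unit mass distribution implied by a 13C abundance
#' `p13`, for running SISA on uncorrected fractions.
#'
#' @param p13 13C abundance.
#' @return Simplex 3-vector `((1-p)^2, 2p(1-p), p^2)`.
#' @export
natural_monomer <- function(p13 = P13C_DEFAULT) {
  c((1 - p13)^2, 2 * p13 * (1 - p13), p13^2)
}

# ---- sisa_fit methods -------------------------------------------------------

#' @export
print.sisa_fit <- function(x, ...) {
  cat(sprintf("SISA fit (%s, %d subunits)%s\n", x$model, x$n_subunits,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  g = %.4f", x$g))
  if (!is.na(x$e)) cat(sprintf("   e = %.4f", x$e))
  cat(sprintf("\n  X = (%.4f, %.4f, %.4f)\n", x$X[1], x$X[2], x$X[3]))
  cat(sprintf("  sse = %.3g over %d isotopologues\n", x$sse, x$n_unmasked))
  invisible(x)
}

#' @export
coef.sisa_fit <- function(object, ...) {
  c(g = object$g, e = object$e,
    X0 = object$X[1], X1 = object$X[2], X2 = object$X[3])
}

#' Predicted isotopologue fractions from a fit
#'
#' Returns the forward-model fractions at the fitted parameters, either over
#' the full ladder (`renormalized = FALSE`) or renormalized over the
#' unmasked set as used in the residuals (`renormalized = TRUE`).
#'
#' @param object a `sisa_fit`.
#' @param renormalized renormalize over unmasked isotopologues.
#' @param ... unused.
#' @return Numeric vector of fractions (NA at masked entries if
#'   renormalized).
#' @export
predict.sisa_fit <- function(object, renormalized = FALSE, ...) {
  if (!object$converged) stop("fit did not converge")
  p <- if (object$model == "elongation") {
    elongation_forward(object$X, object$N, object$g, object$e)
  } else {
    sisa_forward(object$X, object$N, object$g, object$n_subunits)
  }
  if (!renormalized) return(p)
  out <- rep(NA_real_, length(p))
  un <- object$mask & !is.na(object$observed)
  out[un] <- p[un] / sum(p[un])
  out
}

#' @export
residuals.sisa_fit <- function(object, ...) {
  un <- object$mask & !is.na(object$observed)
  f <- object$observed
  f[un] <- f[un] / sum(f[un])
  r <- f - predict(object, renormalized = TRUE)
  r[!un] <- NA_real_
  r
}

#' @export
summary.sisa_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(r^2, na.rm = TRUE))),
            class = "summary.sisa_fit")
}

#' @export
print.summary.sisa_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE = %.3g\n", x$rmse))
  invisible(x)
}

#' Simulate noisy observations from a fitted model
#'
#' Draws `nsim` replicate fraction vectors by adding independent Gaussian
#' noise of standard deviation `sigma` to the fitted fractions, clipping
#' negatives and renormalizing — the same noise model as
#' [noise_gradient_simulation()].
#'
#' @param object a converged `sisa_fit`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param sigma fractional-abundance noise SD.
#' @param ... unused.
#' @return Matrix, `nsim` rows of fraction vectors.
#' @export
simulate.sisa_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.01, ...) {
  p <- predict(object)
  draw <- function() {
    v <- pmax(p + stats::rnorm(length(p), 0, sigma), 0)
    v / sum(v)
  }
  sims <- if (is.null(seed)) {
    t(replicate(nsim, draw()))
  } else {
    .with_seed(seed, t(replicate(nsim, draw())))
  }
  sims
}
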