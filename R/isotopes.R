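# Natural-abundance correction, fractional labeling, pool sizes and
# interference screening against unlabeled control tissue.

#' Terrestrial 13C natural abundance
#' @export
P13C_DEFAULT <- 0.0107

#' Isotopologue abundance distribution of one metabolite in one pixel
#'
#' @param a numeric vector of isotopologue abundances `a_0..a_n` (arbitrary
#'   intensity units; negatives clipped to 0).
#' @param n_carbons carbon count `n`; `length(a)` must be `n_carbons + 1`.
#' @param mask logical vector, `TRUE` = usable isotopologue. Interference-
#'   compromised entries are masked out and excluded from all ratios.
#' @param corrected whether natural-abundance correction has been applied.
#' @return A `labeling_distribution` object.
#' @export
labeling_distribution <- function(a, n_carbons = length(a) - 1L,
                                  mask = rep(TRUE, length(a)),
                                  corrected = FALSE) {
  stopifnot(length(a) == n_carbons + 1L, length(mask) == length(a))
  a <- pmax(as.numeric(a), 0)
  structure(list(a = a, n_carbons = as.integer(n_carbons),
                 mask = as.logical(mask), corrected = corrected),
            class = "labeling_distribution")
}

#' @export
print.labeling_distribution <- function(x, ...) {
  cat(sprintf("Labeling distribution: n = %d, %d/%d usable, %scorrected\n",
              x$n_carbons, sum(x$mask), length(x$a),
              if (x$corrected) "" else "un"))
  f <- fractional_labeling(x)
  cat("  f:", paste(sprintf("%.3f", f), collapse = " "), "\n")
  invisible(x)
}

#' Fractional labeling f_0..f_n
#'
#' Divides each usable isotopologue abundance by the sum over all usable
#' isotopologues, so the result sums to 1 over the unmasked set. Masked
#' entries are returned as `NA` (undefined, not zero).
#'
#' @param dist a [labeling_distribution()].
#' @return Numeric vector of length `n_carbons + 1`.
#' @export
fractional_labeling <- function(dist) {
  tot <- sum(dist$a[dist$mask])
  if (tot <= 0) stop("all unmasked abundances are zero: fractional labeling undefined")
  f <- rep(NA_real_, length(dist$a))
  f[dist$mask] <- dist$a[dist$mask] / tot
  f
}

#' Fractional carbon-atom labeling L
#'
#' The fraction of the metabolite's carbon atoms that carry label:
#' `L = sum(j * a_j) / (n * sum(a_j))` over usable isotopologues. Invariant
#' under uniform scaling of the abundances.
#'
#' @param dist a [labeling_distribution()].
#' @return Scalar in `[0, 1]`.
#' @export
carbon_atom_labeling <- function(dist) {
  tot <- sum(dist$a[dist$mask])
  if (tot <= 0) stop("all unmasked abundances are zero: L undefined")
  j <- (seq_along(dist$a) - 1L)[dist$mask]
  sum(j * dist$a[dist$mask]) / (dist$n_carbons * tot)
}

#' Relative pool-size image
#'
#' Sums the unmasked isotopologue intensities of one target per pixel — the
#' label-summed analogue of a conventional (unlabeled) MSI ion image. Pool
#' sizes are subject to pixel-specific matrix effects; fractional labeling is
#' not.
#'
#' @param stack an [ion_image_stack()].
#' @param target target name or [target_metabolite()].
#' @param mask logical vector over isotopologues (default all TRUE); e.g.
#'   exclude M1 for NAA, or M1/M4/M5 for DESI palmitate.
#' @return `width x height` numeric matrix.
#' @export
pool_size_image <- function(stack, target, mask = NULL) {
  rows <- .target_rows(stack, target)
  if (is.null(mask)) mask <- rep(TRUE, length(rows))
  stopifnot(length(mask) == length(rows))
  sub <- stack$tensor[rows[mask], , , drop = FALSE]
  apply(sub, c(2, 3), sum)
}

#' Natural-abundance correction matrix
#'
#' Column `j` holds the binomial probability pattern with which a molecule
#' carrying `j` tracer-derived labels is observed across total heavy-carbon
#' counts `i = j..n`: the remaining `n - j` carbons each pick up a 13C with
#' probability `p13`. Every column sums to 1; `p13 = 0` gives the identity.
#'
#' @param n_carbons carbon count `n`.
#' @param p13 13C abundance (default terrestrial 0.0107).
#' @return `(n+1) x (n+1)` matrix, `M[i, j] = dbinom(i - j, n - j, p13)`.
#' @export
na_correction_matrix <- function(n_carbons, p13 = P13C_DEFAULT) {
  stopifnot(p13 >= 0, p13 < 1)
  n <- as.integer(n_carbons)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    M[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), n - j, p13)
  }
  M
}

#' Natural-abundance correction of one distribution
#'
#' Deconvolves the natural 13C contribution by solving `M x = a` for the
#' tracer-only isotopologue abundances `x` by non-negative least squares
#' (direct inversion can produce negative isotopologues at low signal). The
#' total abundance is conserved; pixels whose residual exceeds 5% of the
#' total are flagged via the `inconsistent` attribute.
#'
#' @param dist an uncorrected [labeling_distribution()]. Correction precedes
#'   masking; masked entries are imputed as 0 with a warning.
#' @param p13 13C abundance.
#' @return A corrected `labeling_distribution` (mask carried over).
#' @export
na_correct <- function(dist, p13 = P13C_DEFAULT) {
  stopifnot(inherits(dist, "labeling_distribution"))
  if (dist$corrected) stop("distribution is already corrected")
  a <- dist$a
  if (!all(dist$mask)) {
    warning("masked isotopologues imputed as 0 before NA correction")
    a[!dist$mask] <- 0
  }
  M <- na_correction_matrix(dist$n_carbons, p13)
  x <- na_correct_matrix(matrix(a, ncol = 1), M)[, 1]
  out <- labeling_distribution(x, dist$n_carbons, dist$mask, corrected = TRUE)
  resid <- sum(abs(M %*% x - a))
  attr(out, "inconsistent") <- sum(a) > 0 && resid > 0.05 * sum(a)
  out
}

# vectorized core: columns of A are pixels; returns corrected columns,
# rescaled to conserve each column total. When an isotopologue mask is
# given, flagged (interfered) channels are excluded from the least-squares
# residual so a contaminant cannot leak into neighboring isotopologues; the
# rescaling then conserves the unmasked total.
na_correct_matrix <- function(A, M, mask = NULL) {
  out <- matrix(0, nrow(A), ncol(A))
  rows <- if (is.null(mask)) seq_len(nrow(A)) else which(mask)
  Mr <- M[rows, , drop = FALSE]
  # with masked rows the system is underdetermined; a tiny Tikhonov
  # augmentation keeps the active-set solver determinate without
  # perceptibly biasing the solution
  ridge <- length(rows) < ncol(M)
  for (p in seq_len(ncol(A))) {
    a <- A[, p]
    tot <- sum(a[rows])
    if (tot <= 0) next
    if (ridge) {
      lam <- 1e-6 * tot / length(a)
      x <- pracma::lsqnonneg(rbind(Mr, diag(lam, ncol(M))),
                             c(a[rows], numeric(ncol(M))))$x
    } else {
      x <- pracma::lsqnonneg(Mr, a[rows])$x
    }
    sfit <- sum(Mr %*% x)
    if (sfit > 0) x <- x * (tot / sfit)
    out[, p] <- x
  }
  out
}

#' Natural-abundance correction of a whole stack
#'
#' Applies [na_correct()] per pixel and target across an
#' [ion_image_stack()], optionally restricted to tissue pixels.
#'
#' @param stack an [ion_image_stack()].
#' @param p13 13C abundance.
#' @param tissue_mask optional logical `width x height` matrix; pixels
#'   outside it are zeroed.
#' @param iso_masks optional named list (by target) of isotopologue
#'   usability masks (e.g. from [interference_mask()]); flagged channels are
#'   excluded from the correction residual.
#' @return The corrected stack (attribute `corrected = TRUE`).
#' @export
na_correct_stack <- function(stack, p13 = P13C_DEFAULT, tissue_mask = NULL,
                             iso_masks = NULL) {
  cc <- stack$grid$coords
  keep <- if (is.null(tissue_mask)) rep(TRUE, nrow(cc))
          else tissue_mask[cbind(cc$x + 1L, cc$y + 1L)]
  for (t in stack$targets) {
    rows <- .target_rows(stack, t)
    M <- na_correction_matrix(t$n_carbons, p13)
    A <- target_pixel_matrix(stack, t)
    A[, !keep] <- 0
    X <- na_correct_matrix(A, M, mask = iso_masks[[t$name]])
    for (p in seq_len(nrow(cc))) {
      stack$tensor[rows, cc$x[p] + 1L, cc$y[p] + 1L] <- X[, p]
    }
  }
  attr(stack, "corrected") <- TRUE
  stack
}

#' Screen isotopologues for interfering background ions
#'
#' In unlabeled control tissue no isotopologue above M0 should survive
#' natural-abundance correction. For each target and each `k >= 1`, the
#' tissue-mean NA-corrected fractional abundance in the unlabeled stack is
#' computed; values above `threshold` indicate a co-extracted background ion
#' and the isotopologue is flagged for exclusion from the labeled analysis.
#'
#' @param unlabeled_stack an [ion_image_stack()] from unlabeled tissue, or
#'   `NULL` (returns an "unscreened" report rather than a silent pass).
#' @param targets list of [target_metabolite()].
#' @param threshold fraction of unexplained signal above which an
#'   isotopologue is flagged (default 0.02).
#' @param tissue_mask optional logical matrix restricting the mean to tissue.
#' @param p13 13C abundance used for the correction.
#' @return An `interference_report`: data frame (target, k, excess, flagged)
#'   with attributes `threshold` and `status` ("screened"/"unscreened").
#' @export
screen_interferences <- function(unlabeled_stack, targets,
                                 threshold = 0.02, tissue_mask = NULL,
                                 p13 = P13C_DEFAULT) {
  if (inherits(targets, "target_metabolite")) targets <- list(targets)
  if (is.null(unlabeled_stack)) {
    rep_df <- do.call(rbind, lapply(targets, function(t) {
      data.frame(target = t$name, k = 0:t$n_carbons, excess = NA_real_,
                 flagged = FALSE)
    }))
    attr(rep_df, "threshold") <- threshold
    attr(rep_df, "status") <- "unscreened"
    class(rep_df) <- c("interference_report", class(rep_df))
    return(rep_df)
  }
  stopifnot(inherits(unlabeled_stack, "ion_image_stack"))
  if (isTRUE(unlabeled_stack$labeled)) {
    stop("interference screening requires an unlabeled control stack")
  }
  cc <- unlabeled_stack$grid$coords
  keep <- if (is.null(tissue_mask)) rep(TRUE, nrow(cc))
          else tissue_mask[cbind(cc$x + 1L, cc$y + 1L)]
  out <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    t <- targets[[ti]]
    M <- na_correction_matrix(t$n_carbons, p13)
    A <- target_pixel_matrix(unlabeled_stack, t)[, keep, drop = FALSE]
    X <- na_correct_matrix(A, M)
    tot <- colSums(X)
    ok <- tot > 0
    if (!any(ok)) {
      mean_f <- rep(NA_real_, t$n_carbons + 1L)
    } else {
      F <- sweep(X[, ok, drop = FALSE], 2, tot[ok], "/")
      mean_f <- rowMeans(F)
    }
    flag <- !is.na(mean_f) & mean_f > threshold
    flag[1] <- FALSE  # M0 never flagged
    out[[ti]] <- data.frame(target = t$name, k = 0:t$n_carbons,
                            excess = mean_f, flagged = flag)
  }
  rep_df <- do.call(rbind, out)
  rownames(rep_df) <- NULL
  attr(rep_df, "threshold") <- threshold
  attr(rep_df, "status") <- "screened"
  class(rep_df) <- c("interference_report", class(rep_df))
  rep_df
}

#' @export
print.interference_report <- function(x, ...) {
  cat(sprintf("Interference report (%s, threshold %.3g):\n",
              attr(x, "status"), attr(x, "threshold")))
  fl <- x[x$flagged, , drop = FALSE]
  if (nrow(fl) == 0) cat("  no isotopologues flagged\n")
  else for (i in seq_len(nrow(fl))) {
    cat(sprintf("  %s M%d: excess %.4f\n", fl$target[i], fl$k[i], fl$excess[i]))
  }
  invisible(x)
}

#' Isotopologue usability mask from an interference report
#'
#' @param report an `interference_report`.
#' @param target target name.
#' @return Logical vector over M0..Mn, `FALSE` where flagged.
#' @export
interference_mask <- function(report, target) {
  sub <- report[report$target == target, , drop = FALSE]
  if (nrow(sub) == 0) stop("target not in report: ", target)
  !sub$flagged[order(sub$k)]
}
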