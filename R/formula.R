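# Elemental composition handling and theoretical m/z ladders.

# Monoisotopic masses of the elements that occur in the targeted metabolites
# (CODATA/AME values, u). Extend here if a target needs more chemistry.
.MONOISOTOPIC <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268
)

.PROTON_MASS <- 1.007276466  # mass of H+ (H minus one electron), u

#' Mass difference between 13C and 12C
#'
#' The spacing of a carbon isotopologue ladder, in u.
#' @export
C13_C12_DELTA <- 1.0033548

#' Parse a molecular formula
#'
#' Parses a Hill-style elemental composition such as `"C16H32O2"` into a
#' named integer vector of element counts. Only neutral formulas without
#' charges, isotope markers or parentheses are supported.
#'
#' @param formula character scalar, e.g. `"C16H32O2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C16H32O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (!el %in% names(.MONOISOTOPIC)) {
      stop("unknown element symbol '", el, "' in formula '", formula, "'")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula character formula or named count vector from
#'   [parse_formula()].
#' @return Monoisotopic mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.MONOISOTOPIC[names(counts)] * counts)
}

# Supported adducts: neutral monoisotopic mass -> ion m/z.
.ADDUCTS <- list(
  "[M-H]-"  = function(m) m - .PROTON_MASS,
  "[M+H]+"  = function(m) m + .PROTON_MASS,
  "[M+Cl]-" = function(m) m + .MONOISOTOPIC[["Cl"]] + 5.48579909e-4,
  "[M+Na]+" = function(m) m + .MONOISOTOPIC[["Na"]] - 5.48579909e-4
)

#' Theoretical isotopologue m/z ladder for a target metabolite
#'
#' Computes the monoisotopic ion m/z for `formula` + `adduct` and returns the
#' ladder of `n_carbons + 1` m/z values spaced by the 13C-12C mass difference
#' (1.0033548 u), i.e. the expected positions of the M0..Mn isotopologues of a
#' 13C-labeled metabolite.
#'
#' @param formula molecular formula of the neutral metabolite.
#' @param adduct one of `"[M-H]-"`, `"[M+H]+"`, `"[M+Cl]-"`, `"[M+Na]+"`.
#' @param n_carbons number of carbon atoms that can carry label; must not
#'   exceed the carbon count of the formula.
#' @return Numeric vector of length `n_carbons + 1`, strictly increasing.
#' @examples
#' build_target_ladder("C16H32O2", "[M-H]-", 16)[1]  # palmitate M0, ~255.2330
#' @export
build_target_ladder <- function(formula, adduct = "[M-H]-", n_carbons) {
  counts <- parse_formula(formula)
  n_carbons <- as.integer(n_carbons)
  nc_formula <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_carbons > nc_formula) {
    stop("n_carbons (", n_carbons, ") exceeds carbons in formula (",
         nc_formula, ")")
  }
  if (!adduct %in% names(.ADDUCTS)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  mz0 <- .ADDUCTS[[adduct]](monoisotopic_mass(counts))
  unname(mz0 + (0:n_carbons) * C13_C12_DELTA)
}

#' Define a target metabolite
#'
#' Bundles the information the pipeline needs per metabolite: its formula,
#' adduct, labeled-carbon count (the isotopologue ladder length is
#' `n_carbons + 1`) and, for polymer targets fitted with ISA/SISA, the number
#' of 2-carbon precursor subunits (8 for palmitate, 9 for stearate).
#'
#' @param name display name.
#' @param formula neutral molecular formula.
#' @param adduct ion species; see [build_target_ladder()].
#' @param n_carbons labeled carbon count.
#' @param n_subunits acetyl-CoA subunit count, or `NA` for non-polymer
#'   targets. Must satisfy `n_subunits <= ceiling(n_carbons / 2)`.
#' @return A `target_metabolite` object (list with the above fields plus
#'   `mz_ladder`).
#' @examples
#' target_metabolite("palmitate", "C16H32O2", "[M-H]-", 16, 8)
#' @export
target_metabolite <- function(name, formula, adduct = "[M-H]-",
                              n_carbons, n_subunits = NA_integer_) {
  n_carbons <- as.integer(n_carbons)
  n_subunits <- as.integer(n_subunits)
  if (!is.na(n_subunits) && n_subunits > ceiling(n_carbons / 2)) {
    stop("n_subunits (", n_subunits, ") exceeds ceiling(n_carbons/2)")
  }
  ladder <- build_target_ladder(formula, adduct, n_carbons)
  structure(
    list(name = name, formula = formula, adduct = adduct,
         n_carbons = n_carbons, n_subunits = n_subunits,
         mz_ladder = ladder),
    class = "target_metabolite"
  )
}

#' @export
print.target_metabolite <- function(x, ...) {
  cat(sprintf("Target metabolite: %s (%s, %s)\n", x$name, x$formula, x$adduct))
  cat(sprintf("  carbons: %d; subunits: %s; M0 m/z: %.4f\n",
              x$n_carbons,
              if (is.na(x$n_subunits)) "-" else x$n_subunits,
              x$mz_ladder[1]))
  invisible(x)
}

#' Read a target metabolite list
#'
#' Reads a tab- or comma-delimited file with columns `name`, `formula`,
#' `adduct`, `n_carbons`, `n_subunits` (the last may be empty or NA for
#' non-polymer targets).
#'
#' @param path file path.
#' @return List of [target_metabolite()] objects.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop("target list not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE)
  need <- c("name", "formula", "adduct", "n_carbons")
  if (!all(need %in% names(df))) {
    stop("target list must have columns: ", paste(need, collapse = ", "))
  }
  if (!"n_subunits" %in% names(df)) df$n_subunits <- NA_integer_
  lapply(seq_len(nrow(df)), function(i) {
    target_metabolite(df$name[i], df$formula[i], df$adduct[i],
                      df$n_carbons[i], df$n_subunits[i])
  })
}
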