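# Molecular-formula arithmetic for HRESIMS verification: parsing, monoisotopic
# and adduct masses, ring-plus-double-bond equivalents, and formula search.

# Monoisotopic masses of the most abundant isotope (IUPAC 2021 atomic masses),
# embedded so results are reproducible offline.
.MONOISOTOPIC <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928,
  P  = 30.97376151,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904473,
  F  = 18.99840320,
  Si = 27.9769265327,
  K  = 38.9637069
)

# CODATA electron mass in Da; subtracted once per positive charge so that
# "calcd for [M+H]+" values match what mass spectrometrists print.
.ELECTRON_MASS <- 0.00054857990946

# Valence contribution of each element to ring-plus-double-bond equivalents.
.RDBE_CONTRIB <- c(
  C = 1, Si = 1,
  H = -0.5, F = -0.5, Cl = -0.5, Br = -0.5, I = -0.5,
  N = 0.5, P = 0.5,
  O = 0, S = 0
)

#' Create a molecular formula object
#'
#' @param counts Named integer vector of element counts (names are element
#'   symbols from the embedded isotope table).
#' @param charge Integer charge; 0 for a neutral molecule, +1 for a
#'   protonated cation.
#' @return An object of class `molecular_formula`.
#' @export
molecular_formula <- function(counts = integer(), charge = 0L) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be a named vector of element counts")
    unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("element counts must be non-negative integers")
  }
  structure(
    list(counts = as.integer(round(counts)) |> stats::setNames(names(counts)),
         charge = as.integer(charge)),
    class = "molecular_formula"
  )
}

#' Parse a Hill-notation molecular formula string
#'
#' Accepts element symbols in any order (e.g. both `"C26H35O5N3S"` and
#' `"C26H36N3O5S"`), each optionally followed by an integer count.
#'
#' @param text Formula string such as `"C26H36N3O5S"`.
#' @param charge Charge to attach to the parsed formula (default 0).
#' @return A [molecular_formula()] object.
#' @examples
#' parse_formula("C26H36N3O5S")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, charge = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(molecular_formula(charge = charge))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", sQuote(text))
  counts <- integer()
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.MONOISOTOPIC))
      stop("unknown element symbol ", sQuote(sym), " in ", sQuote(text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  molecular_formula(counts, charge)
}

.as_formula <- function(x, charge = NULL) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(inherits(x, "molecular_formula"))
  if (!is.null(charge)) x$charge <- as.integer(charge)
  x
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (!length(x$counts)) return("(empty)")
  # Hill order: C, H, then alphabetical
  syms <- names(x$counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  body <- paste0(ord, ifelse(x$counts[ord] > 1, x$counts[ord], ""),
                 collapse = "")
  chg <- if (x$charge > 0) paste0("^", x$charge, "+")
         else if (x$charge < 0) paste0("^", abs(x$charge), "-") else ""
  paste0(body, chg)
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums the masses of the most abundant isotope of every element and subtracts
#' one electron mass per unit of positive charge (adds it per negative unit),
#' so charged results are ion m/z values on the scale mass spectrometrists
#' report.
#'
#' @param formula A [molecular_formula()] or formula string.
#' @return Mass (or m/z for charged species) in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass(adduct_formula("C26H35N3O5S", "[M+H]+"))
#' @export
monoisotopic_mass <- function(formula) {
  f <- .as_formula(formula)
  if (!length(f$counts)) return(0 - f$charge * .ELECTRON_MASS)
  m <- sum(.MONOISOTOPIC[names(f$counts)] * f$counts)
  m - f$charge * .ELECTRON_MASS
}

.ADDUCTS <- list(
  "[M+H]+"  = list(add = c(H = 1L),  charge = +1L),
  "[M+Na]+" = list(add = c(Na = 1L), charge = +1L),
  "[M-H]-"  = list(add = c(H = -1L), charge = -1L)
)

.normalize_adduct <- function(adduct) {
  # accept the typographic minus sign
  a <- gsub("−", "-", adduct)
  if (!a %in% names(.ADDUCTS))
    stop("unsupported adduct ", sQuote(adduct), "; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  a
}

#' Apply an ionization adduct to a neutral formula
#'
#' @param neutral Neutral [molecular_formula()] or string.
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M-H]-"` (a Unicode minus
#'   is accepted).
#' @return The ion's `molecular_formula`, with charge set.
#' @export
adduct_formula <- function(neutral, adduct) {
  f <- .as_formula(neutral)
  if (f$charge != 0L) stop("adducts apply to neutral formulas")
  spec <- .ADDUCTS[[.normalize_adduct(adduct)]]
  counts <- f$counts
  for (sym in names(spec$add)) {
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) +
      spec$add[[sym]]
    if (counts[sym] < 0)
      stop("adduct ", adduct, " removes more ", sym, " than present")
  }
  molecular_formula(counts, spec$charge)
}

#' m/z of a neutral formula under an ionization adduct
#'
#' @inheritParams adduct_formula
#' @return m/z in Th (electron-mass corrected).
#' @examples
#' adduct_mz("C26H35N3O5S", "[M+H]+") # 502.2370, the protonated molecular ion
#' @export
adduct_mz <- function(neutral, adduct) {
  monoisotopic_mass(adduct_formula(neutral, adduct))
}

#' Ring-plus-double-bond equivalents (degrees of unsaturation)
#'
#' RDBE = 1 + sum of per-element valence contributions (C, Si: +1; H and
#' halogens: -1/2; N, P: +1/2; O, S: 0).
#'
#' @param formula A [molecular_formula()] or formula string.
#' @return RDBE as a double (can be half-integral for odd-electron ions).
#' @examples
#' rdbe("C26H35N3O5S") # 11
#' @export
rdbe <- function(formula) {
  f <- .as_formula(formula)
  if (!length(f$counts)) return(1)
  undef <- setdiff(names(f$counts), names(.RDBE_CONTRIB))
  if (length(undef))
    stop("no RDBE valence contribution defined for: ",
         paste(undef, collapse = ", "))
  1 + sum(.RDBE_CONTRIB[names(f$counts)] * f$counts)
}

#' Search elemental compositions matching an observed m/z
#'
#' Exhaustively enumerates compositions within per-element count ranges,
#' keeps those whose theoretical m/z under `adduct` falls within
#' `tolerance_ppm` of the query and whose RDBE is non-negative, and ranks
#' them by absolute mass error.
#'
#' @param mz Observed m/z in Th.
#' @param adduct Adduct string as in [adduct_mz()], or `"neutral"` to match
#'   the neutral monoisotopic mass directly.
#' @param tolerance_ppm Mass tolerance in parts per million (> 0).
#' @param element_ranges Named list of `c(min, max)` integer count ranges,
#'   e.g. `list(C = c(20, 30), H = c(30, 40))`.
#' @return A data frame with columns `formula`, `mz_calc`, `error_ppm`,
#'   `rdbe`, sorted by `abs(error_ppm)`; zero rows when nothing matches.
#' @export
formula_search <- function(mz, adduct = "[M+H]+", tolerance_ppm = 5,
                           element_ranges = list()) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tolerance_ppm > 0)
  if (!length(element_ranges))
    return(data.frame(formula = character(), mz_calc = numeric(),
                      error_ppm = numeric(), rdbe = numeric()))
  syms <- names(element_ranges)
  unknown <- setdiff(syms, names(.RDBE_CONTRIB))
  if (length(unknown))
    stop("formula_search supports RDBE-defined elements only; offending: ",
         paste(unknown, collapse = ", "))
  grids <- lapply(element_ranges, function(r) {
    stopifnot(length(r) == 2L, all(is.finite(r)), r[1] <= r[2])
    seq.int(r[1], r[2])
  })
  combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  mass <- combos %*% .MONOISOTOPIC[syms]
  rdbe_all <- 1 + combos %*% .RDBE_CONTRIB[syms]
  neutral_ok <- adduct == "neutral"
  if (neutral_ok) {
    mz_calc <- as.numeric(mass)
  } else {
    spec <- .ADDUCTS[[.normalize_adduct(adduct)]]
    delta <- sum(.MONOISOTOPIC[names(spec$add)] * spec$add) -
      spec$charge * .ELECTRON_MASS
    mz_calc <- as.numeric(mass) + delta
  }
  err_ppm <- (mz_calc - mz) / mz * 1e6
  keep <- abs(err_ppm) <= tolerance_ppm & as.numeric(rdbe_all) >= 0
  if (!any(keep))
    return(data.frame(formula = character(), mz_calc = numeric(),
                      error_ppm = numeric(), rdbe = numeric()))
  combos <- combos[keep, , drop = FALSE]
  out <- data.frame(
    formula = apply(combos, 1L, function(row) {
      format(molecular_formula(stats::setNames(as.integer(row), syms)))
    }),
    mz_calc = mz_calc[keep],
    error_ppm = err_ppm[keep],
    rdbe = as.numeric(rdbe_all)[keep]
  )
  out[order(abs(out$error_ppm)), , drop = FALSE]
}
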