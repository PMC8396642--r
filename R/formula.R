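#' Elemental formulas
#'
#' A `chem_formula` is a named integer vector of non-negative element counts
#' over the supported CHNOS table, carried in Hill order (C, H, then the
#' remaining elements alphabetically). It is the currency of every mass
#' computation in the package: parsing Table-style formula strings,
#' elemental arithmetic for biotransformation deltas, monoisotopic mass and
#' protonated m/z.
#'
#' @param text Formula string in Hill notation, e.g. `"C9H10N2S"`. An
#'   element symbol without a trailing number has implicit count 1.
#' @return `parse_formula()` returns a `chem_formula`; `format_formula()`
#'   its canonical Hill-order string. `parse_formula(format_formula(f))`
#'   is the identity.
#' @examples
#' f <- parse_formula("C9H10N2S")   # bemethyl
#' format_formula(f)
#' monoisotopic_mass(f)
#' protonated_mz(f)                 # 179.0637, the [M+H]+ of bemethyl
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("[[:space:]]", "", text)
  counts <- .zero_counts()
  if (nzchar(txt)) {
    # tokens: one-or-two-letter element symbol + optional count
    m <- gregexpr("[A-Z][a-z]?[0-9]*", txt)[[1]]
    tokens <- regmatches(txt, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(txt) || m[1] != 1L) {
      bad <- substr(txt, 1L, 8L)
      stop("malformed formula near '", bad, "' in '", text, "'", call. = FALSE)
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      num <- sub("^[A-Za-z]+", "", tok)
      if (!sym %in% .supported_elements()) {
        stop("unknown element symbol '", sym, "' in '", text, "'", call. = FALSE)
      }
      n <- if (nzchar(num)) as.integer(num) else 1L
      counts[sym] <- counts[sym] + n
    }
  }
  new_formula(counts)
}

.zero_counts <- function() {
  counts <- integer(length(.supported_elements()))
  names(counts) <- .supported_elements()
  counts
}

#' Construct a formula from element counts
#'
#' @param counts named integer vector (names are element symbols); or a
#'   `chem_formula` (returned unchanged).
#' @export
as_formula <- function(counts) {
  if (inherits(counts, "chem_formula")) return(counts)
  if (is.character(counts)) return(parse_formula(counts))
  stopifnot(!is.null(names(counts)))
  out <- .zero_counts()
  unknown <- setdiff(names(counts), .supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out[names(counts)] <- as.integer(counts)
  new_formula(out)
}

new_formula <- function(counts) {
  if (any(counts < 0)) {
    stop("negative element count in formula", call. = FALSE)
  }
  structure(counts, class = "chem_formula")
}

#' @rdname parse_formula
#' @param f A `chem_formula`.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  hill <- c("C", "H", sort(setdiff(names(f), c("C", "H"))))
  parts <- vapply(hill, function(el) {
    n <- f[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  all(unclass(as_formula(e1)) == unclass(as_formula(e2)))
}

#' Elemental arithmetic
#'
#' `apply_delta()` adds and removes atoms from a formula, the primitive the
#' biotransformation rule engine is built on (e.g. S-oxidation is `add =
#' "O"`; oxidative S-de-ethylation of the alpha-hydroxylated intermediate is
#' `remove = "C2H4O"`). A delta that would drive any element below zero is an
#' infeasible transformation and raises an error of class
#' `bemetab_infeasible`.
#'
#' @param f,add,remove Formulas (strings or `chem_formula`). `add` and
#'   `remove` default to the empty formula.
#' @return A `chem_formula`, `f + add - remove`.
#' @examples
#' apply_delta(parse_formula("C9H10N2S"), add = "O")        # sulfoxide
#' apply_delta(parse_formula("C9H10N2S"), remove = "C2H4")  # de-ethylation
#' @export
apply_delta <- function(f, add = "", remove = "") {
  f <- as_formula(f); a <- as_formula(add); r <- as_formula(remove)
  res <- unclass(f) + unclass(a) - unclass(r)
  if (any(res < 0)) {
    short <- names(res)[res < 0]
    stop(structure(
      class = c("bemetab_infeasible", "error", "condition"),
      list(message = paste0("infeasible transformation: formula ",
                            format_formula(f), " lacks ",
                            paste(short, collapse = ", ")),
           call = sys.call(-1))))
  }
  new_formula(res)
}

#' Monoisotopic mass
#'
#' Sum over elements of count times the lightest-isotope mass from the
#' packaged isotope table.
#'
#' @param f Formula (string or `chem_formula`).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * .mono_masses()[names(f)])
}

#' m/z of the protonated molecule
#'
#' `[M+H]+` m/z of a neutral: monoisotopic mass plus the proton mass
#' (1.00727646 Da). Positive-mode electrospray of the urinary metabolites
#' considered here produces singly protonated even-electron cations only.
#'
#' @param neutral Neutral formula (string or `chem_formula`).
#' @return m/z in Th (full precision; round at presentation time).
#' @examples
#' round(protonated_mz("C9H10N2S"), 4)  # bemethyl precursor ion
#' @export
protonated_mz <- function(neutral) {
  monoisotopic_mass(neutral) + PROTON_MASS
}

#' m/z of an ion formula under an electron-handling convention
#'
#' The even-electron cation convention (`"cation"`) is the physically
#' correct one: the m/z of an ion whose atomic composition is `ion_formula`
#' is the atom-mass sum minus one electron mass. Published tables are not
#' always consistent about the electron (or the proton): `"as-written"`
#' takes the plain atom sum, `"protonated"` adds a proton to the written
#' composition. The product-ion annotator tries these interpretations in
#' order and records which one matched.
#'
#' @param ion_formula Atomic composition of the ion (string or
#'   `chem_formula`).
#' @param convention One of `"cation"`, `"as-written"`, `"protonated"`.
#' @return m/z in Th for charge +1.
#' @export
ion_mz <- function(ion_formula,
                   convention = c("cation", "as-written", "protonated")) {
  convention <- match.arg(convention)
  m <- monoisotopic_mass(ion_formula)
  switch(convention,
         "cation"     = m - ELECTRON_MASS,
         "as-written" = m,
         "protonated" = m + PROTON_MASS)
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 over the CHNOS set (O and S are divalent and do
#' not contribute). Half-integer values flag odd-electron ion compositions;
#' the candidate filter uses RDBE of the neutral.
#'
#' @param f Formula (string or `chem_formula`).
#' @return RDBE (possibly half-integer).
#' @examples
#' rdbe("C9H10N2S")  # 6: benzimidazole ring system
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  f[["C"]] - f[["H"]] / 2 + f[["N"]] / 2 + 1
}

#' Signed ppm mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`, the accuracy currency of
#' high-resolution MS.
#'
#' @param observed,theoretical m/z values in Th.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Ion species
#'
#' A charged species: atomic composition of the ion (including any added
#' proton), charge (always +1 here) and a display label.
#'
#' @param ion_formula Atomic composition of the ion.
#' @param charge Positive integer charge.
#' @param label Display label, e.g. `"[M+H]+"`.
#' @export
ion_species <- function(ion_formula, charge = 1L, label = NULL) {
  ion_formula <- as_formula(ion_formula)
  stopifnot(charge >= 1L)
  if (is.null(label)) label <- paste0("[", format_formula(ion_formula), "]+")
  structure(list(ion_formula = ion_formula, charge = as.integer(charge),
                 label = label),
            class = "ion_species")
}

#' Protonated ion species of a neutral
#'
#' @param neutral Neutral formula.
#' @export
protonated_ion <- function(neutral) {
  neutral <- as_formula(neutral)
  ion_species(apply_delta(neutral, add = "H"),
              label = paste0("[", format_formula(neutral), "+H]+"))
}

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion> ", x$label, "  m/z ",
      sprintf("%.4f", ion_mz(x$ion_formula, "cation")), "\n", sep = "")
  invisible(x)
}
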