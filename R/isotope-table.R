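#' Packaged isotope masses and abundances
#'
#' Fixed table of isotope masses (Da) and natural abundances for the CHNOS
#' element set, plus the proton and electron mass constants used for ion m/z
#' arithmetic. Values are pinned in the package so that every mass computed
#' by [monoisotopic_mass()], [protonated_mz()] and [formula_pattern()] is
#' reproducible independently of external reference tables.
#'
#' @format A list with one entry per element symbol; each entry is a
#'   data.frame with columns `mass` (Da, strictly increasing) and
#'   `abundance` (fractions summing to 1 within 1e-9).
#' @seealso [monoisotopic_mass()], [formula_pattern()]
#' @export
isotope_table <- function() .BEMETAB_ISOTOPES

# abundances per element sum to 1 exactly by construction of the light isotope
.BEMETAB_ISOTOPES <- list(
  C = data.frame(
    mass      = c(12.0, 13.00335484),
    abundance = c(1 - 0.0107, 0.0107)
  ),
  H = data.frame(
    mass      = c(1.00782503207, 2.01410177812),
    abundance = c(1 - 0.000115, 0.000115)
  ),
  N = data.frame(
    mass      = c(14.00307401, 15.00010890),
    abundance = c(1 - 0.00364, 0.00364)
  ),
  O = data.frame(
    mass      = c(15.99491462, 16.99913176, 17.99915961),
    abundance = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205)
  ),
  S = data.frame(
    mass      = c(31.97207100, 32.97145876, 33.96786690),
    abundance = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
  )
)

#' @rdname isotope_table
#' @export
PROTON_MASS <- 1.00727646

#' @rdname isotope_table
#' @export
ELECTRON_MASS <- 0.00054858

.supported_elements <- function() names(.BEMETAB_ISOTOPES)

# monoisotopic = lightest isotope for CHNOS (also the most abundant)
.mono_masses <- function() {
  vapply(.BEMETAB_ISOTOPES, function(tab) tab$mass[1L], numeric(1))
}
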