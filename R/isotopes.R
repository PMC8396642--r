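#' Isotopologue pattern of an ion or neutral formula
#'
#' Exact multinomial convolution of the per-element isotope distributions of
#' the packaged table, aggregated into unit-mass bins (nominal offsets k = 0,
#' 1, ... from the monoisotopic peak) and truncated at `max_offset`. For the
#' CHNOS elements every heavy isotope shifts the nominal mass by exactly its
#' neutron count, so unit-mass binning within +/-0.3 Da of each integer
#' offset is exact; fine structure such as the 34S versus 13C2 splitting of
#' M+2 is aggregated, which is how unit-resolution isotope reasoning on
#' metabolite spectra is done.
#'
#' @param ion An [ion_species()], a `chem_formula`, or a formula string. An
#'   `ion_species` is treated as a +1 cation (one electron mass subtracted
#'   from every bin mass); a bare formula is treated as a neutral.
#' @param max_offset Largest nominal offset k to keep (default 4).
#' @param normalize `"base"` scales the monoisotopic bin to 100;
#'   `"probability"` keeps raw isotopologue probabilities (they sum to at
#'   most 1; exactly 1 before truncation).
#' @return An `isotope_pattern`: data.frame with columns `offset`, `mass`
#'   (abundance-weighted mean mass of the bin, Da), `intensity`.
#' @examples
#' # M4 precursor ion: the M+2 bin is ~10% of the base peak (two sulfurs)
#' p <- formula_pattern(protonated_ion("C9H10N2O4S2"), max_offset = 2)
#' round(m_plus_k_ratio(p, 2) * 100)
#' @export
formula_pattern <- function(ion, max_offset = 4L,
                            normalize = c("base", "probability")) {
  normalize <- match.arg(normalize)
  stopifnot(max_offset >= 0L)
  is_ion <- inherits(ion, "ion_species")
  f <- if (is_ion) ion$ion_formula else as_formula(ion)

  nb <- max_offset + 1L
  # p[k+1]: probability of nominal offset k; pm[k+1]: prob-weighted mass
  p <- c(1, rep(0, max_offset))
  pm <- rep(0, nb)
  for (el in names(f)) {
    n <- f[[el]]
    if (n == 0L) next
    tab <- .BEMETAB_ISOTOPES[[el]]
    off <- round(tab$mass - tab$mass[1L])
    ap <- rep(0, nb); apm <- rep(0, nb)
    keep <- off <= max_offset
    ap[off[keep] + 1L] <- tab$abundance[keep]
    apm[off[keep] + 1L] <- tab$abundance[keep] * tab$mass[keep]
    for (i in seq_len(n)) {
      res_p <- rep(0, nb); res_pm <- rep(0, nb)
      for (k in seq_len(nb)) {
        j <- seq_len(k)
        res_p[k] <- sum(p[j] * ap[k - j + 1L])
        res_pm[k] <- sum(p[j] * apm[k - j + 1L] + pm[j] * ap[k - j + 1L])
      }
      p <- res_p; pm <- res_pm
    }
  }
  mass <- ifelse(p > 0, pm / p, NA_real_)
  if (is_ion) mass <- mass - ELECTRON_MASS
  intensity <- if (normalize == "base") 100 * p / p[1L] else p
  structure(
    data.frame(offset = 0:max_offset, mass = mass, intensity = intensity),
    class = c("isotope_pattern", "data.frame"),
    normalize = normalize)
}

#' Intensity ratio of the M+k isotopologue to the monoisotopic peak
#'
#' @param p An `isotope_pattern`.
#' @param k Nominal offset; must be within the computed range.
#' @return `intensity(M+k) / intensity(M)` as a fraction.
#' @export
m_plus_k_ratio <- function(p, k) {
  stopifnot(inherits(p, "isotope_pattern"))
  if (!k %in% p$offset) {
    stop("offset k = ", k, " beyond computed pattern (max ",
         max(p$offset), ")", call. = FALSE)
  }
  p$intensity[p$offset == k] / p$intensity[p$offset == 0L]
}

#' Infer the sulfur count from an observed M+2 ratio
#'
#' 34S (4.25% abundance, +2 Da) dominates the M+2 isotopologue of
#' sulfur-bearing ions, so the observed M+2/M ratio pins down the number of
#' sulfur atoms: the estimator returns the s in 0..max_s whose predicted
#' M+2/M ratio for `backbone` plus s sulfurs is closest to the observation
#' (ties broken toward smaller s). Only M+2 is used; M+1 carries mostly 13C
#' information and is noisier in practice.
#'
#' @param observed_m2_ratio Observed M+2/M as a fraction in `[0, 1)`.
#' @param backbone Sulfur-free formula of the rest of the ion.
#' @param max_s Largest sulfur count searched (default 4; metabolites of a
#'   two-sulfur parent cannot exceed this).
#' @return Integer sulfur count.
#' @examples
#' estimate_sulfur_count(0.10, "C9H11N2O4")  # 2, as for metabolite M4
#' @export
estimate_sulfur_count <- function(observed_m2_ratio, backbone, max_s = 4L) {
  stopifnot(observed_m2_ratio >= 0, observed_m2_ratio < 1)
  backbone <- as_formula(backbone)
  if (backbone[["S"]] != 0L) {
    stop("backbone must be sulfur-free; got ", format_formula(backbone),
         call. = FALSE)
  }
  err <- vapply(0:max_s, function(s) {
    f <- apply_delta(backbone, add = as_formula(c(S = s)))
    abs(m_plus_k_ratio(formula_pattern(f, max_offset = 2L), 2L) -
          observed_m2_ratio)
  }, numeric(1))
  # which.min returns the first (smallest s) among ties
  (0:max_s)[which.min(err)]
}
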