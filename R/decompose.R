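#' Element bounds for formula decomposition
#'
#' Search-space configuration for [decompose_mz()]: inclusive per-element
#' count ranges, the mass tolerance in ppm, and the RDBE range applied by
#' [filter_candidates()]. The defaults cover the bemethyl metabolite space
#' (CHNOS, up to a glucuronide-sized conjugate) at an Orbitrap-class 5 ppm
#' tolerance.
#'
#' @param C,H,N,O,S Length-2 integer vectors `c(min, max)`.
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param rdbe_range Allowed RDBE interval for the neutral candidate.
#' @export
element_bounds <- function(C = c(0L, 20L), H = c(0L, 30L), N = c(0L, 5L),
                           O = c(0L, 8L), S = c(0L, 3L), tol_ppm = 5,
                           rdbe_range = c(0, 25)) {
  stopifnot(tol_ppm > 0)
  b <- list(C = C, H = H, N = N, O = O, S = S)
  for (el in names(b)) {
    stopifnot(length(b[[el]]) == 2L, b[[el]][1] <= b[[el]][2],
              b[[el]][1] >= 0L)
  }
  structure(list(counts = b, tol_ppm = tol_ppm, rdbe_range = rdbe_range),
            class = "element_bounds")
}

#' Candidate molecular formulas for an accurate m/z
#'
#' Exhaustive decomposition of a query `[M+H]+` m/z over the CHNOS bounds:
#' every neutral formula within the bounds whose protonated m/z lies within
#' `tol_ppm` of the query is returned, sorted by absolute ppm error, ties
#' broken by fewer heteroatoms (N+O+S), then by Hill string. This is the
#' transparent equivalent of the "generate molecular formulas from the
#' characteristic ions" step of commercial metabolite-identification
#' software. The search prunes on partial mass but is provably exhaustive
#' within the bounds.
#'
#' @param query_mz Observed m/z of the protonated molecule (Th, > 0).
#' @param bounds An [element_bounds()].
#' @return data.frame with columns `formula`, `theoretical_mz`, `ppm`,
#'   `rdbe` (possibly zero rows). The empty formula (bare proton) is never
#'   returned as a candidate.
#' @examples
#' head(decompose_mz(179.0638, element_bounds()))
#' @export
decompose_mz <- function(query_mz, bounds = element_bounds()) {
  stopifnot(query_mz > 0)
  b <- bounds$counts
  target <- query_mz - PROTON_MASS  # neutral monoisotopic mass
  tol_da <- bounds$tol_ppm * 1e-6 * query_mz
  mono <- .mono_masses()

  rows <- list()
  # nested loops with partial-mass pruning; heaviest-first order
  for (nC in b$C[1]:b$C[2]) {
    mC <- nC * mono[["C"]]
    if (mC > target + tol_da) break
    for (nS in b$S[1]:b$S[2]) {
      mS <- mC + nS * mono[["S"]]
      if (mS > target + tol_da) break
      for (nO in b$O[1]:b$O[2]) {
        mO <- mS + nO * mono[["O"]]
        if (mO > target + tol_da) break
        for (nN in b$N[1]:b$N[2]) {
          mN <- mO + nN * mono[["N"]]
          if (mN > target + tol_da) break
          # solve the hydrogen count directly
          nH <- round((target - mN) / mono[["H"]])
          for (h in unique(pmax(b$H[1], pmin(b$H[2], nH + (-1:1))))) {
            m <- mN + h * mono[["H"]]
            if (abs(m - target) <= tol_da && (nC + h + nN + nO + nS) > 0L) {
              rows[[length(rows) + 1L]] <-
                c(C = nC, H = h, N = nN, O = nO, S = nS)
            }
          }
        }
      }
    }
  }
  cand <- unique(do.call(rbind, rows))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(formula = character(), theoretical_mz = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  }
  fl <- apply(cand, 1L, function(r) as_formula(r), simplify = FALSE)
  out <- data.frame(
    formula = vapply(fl, format_formula, character(1)),
    theoretical_mz = vapply(fl, protonated_mz, numeric(1)),
    rdbe = vapply(fl, rdbe, numeric(1))
  )
  out$ppm <- ppm_error(query_mz, out$theoretical_mz)
  hetero <- cand[, "N"] + cand[, "O"] + cand[, "S"]
  ord <- order(abs(out$ppm), hetero, out$formula)
  out <- out[ord, c("formula", "theoretical_mz", "ppm", "rdbe")]
  rownames(out) <- NULL
  out
}

#' Filter decomposition candidates on RDBE
#'
#' Removes candidates whose neutral RDBE falls outside `rdbe_range`;
#' preserves order. A half-integer RDBE on a neutral CHNOS formula is
#' impossible by construction (H and N parities), so the filter is in
#' practice a sanity range on ring/double-bond count.
#'
#' @param cands data.frame from [decompose_mz()].
#' @param rdbe_range Allowed inclusive interval.
#' @export
filter_candidates <- function(cands, rdbe_range = c(0, 25)) {
  if (nrow(cands) == 0L) return(cands)
  keep <- cands$rdbe >= rdbe_range[1] & cands$rdbe <= rdbe_range[2]
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
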