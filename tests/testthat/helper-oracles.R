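# Independent oracles used across the suite. These deliberately avoid the
# package's own convolution / decomposition code paths.

# exhaustive isotopologue enumeration: every per-atom isotope assignment,
# binned by nominal mass offset
enum_isotope_pattern <- function(f, max_offset = 3L) {
  f <- bemetab::as_formula(f)
  it <- bemetab::isotope_table()
  atoms <- rep(names(f), unclass(f))
  stopifnot(length(atoms) > 0L)
  grid <- as.matrix(expand.grid(lapply(atoms, function(el) {
    seq_len(nrow(it[[el]]))
  })))
  base <- sum(vapply(atoms, function(el) it[[el]]$mass[1], numeric(1)))
  p <- rep(0, max_offset + 1L)
  for (r in seq_len(nrow(grid))) {
    pr <- 1; m <- 0
    for (j in seq_along(atoms)) {
      el <- atoms[j]; k <- grid[r, j]
      pr <- pr * it[[el]]$abundance[k]
      m <- m + it[[el]]$mass[k]
    }
    off <- round(m - base)
    if (off <= max_offset) p[off + 1L] <- p[off + 1L] + pr
  }
  100 * p / p[1L]
}

# brute-force formula decomposition over the full grid of element counts
brute_decompose <- function(query_mz, bounds = bemetab::element_bounds()) {
  b <- bounds$counts
  grid <- expand.grid(C = b$C[1]:b$C[2], H = b$H[1]:b$H[2],
                      N = b$N[1]:b$N[2], O = b$O[1]:b$O[2],
                      S = b$S[1]:b$S[2])
  it <- bemetab::isotope_table()
  mono <- vapply(it, function(tab) tab$mass[1], numeric(1))
  mass <- as.matrix(grid) %*% mono[colnames(grid)]
  mz <- mass + bemetab::PROTON_MASS
  ppm <- (query_mz - mz) / mz * 1e6
  keep <- abs(ppm) <= bounds$tol_ppm & rowSums(grid) > 0
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(character())
  apply(grid, 1L, function(r) {
    bemetab::format_formula(bemetab::as_formula(r))
  })
}

# random CHNOS formula with at least one atom
random_formula <- function(maxC = 12, maxH = 20, maxN = 4, maxO = 6,
                           maxS = 3) {
  repeat {
    counts <- c(C = sample(0:maxC, 1), H = sample(0:maxH, 1),
                N = sample(0:maxN, 1), O = sample(0:maxO, 1),
                S = sample(0:maxS, 1))
    if (sum(counts) > 0) return(bemetab::as_formula(counts))
  }
}

# random proper rigid transform (rotation + translation) applied to a
# 3-column coordinate matrix
random_rigid_transform <- function(xyz) {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 10)
  sweep(xyz %*% R, 2, -tr)
}

table2_assigned <- function() {
  data.frame(
    compound = c("bemethyl", "M1a", "M1b", "M2a", "M2b", "M3a", "M3b",
                 "M4", "M6"),
    mz = c(179.0638, 151.0325, 151.0325, 195.0587, 195.0587, 227.0485,
           227.0485, 275.0155, 371.0908),
    formula = c("C9H10N2S", "C7H6N2S", "C7H6N2S", "C9H10N2OS", "C9H10N2OS",
                "C9H10N2O3S", "C9H10N2O3S", "C9H10N2O4S2", "C15H18N2O7S"),
    stringsAsFactors = FALSE)
}
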