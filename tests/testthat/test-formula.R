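test_that("formula parsing reads Hill strings and rejects bad input", {
  expect_equal(unclass(parse_formula("C9H10N2S"))[c("C", "H", "N", "S")],
               c(C = 9L, H = 10L, N = 2L, S = 1L))
  expect_equal(unclass(parse_formula("S"))[["S"]], 1L)
  f5 <- parse_formula("C12H13N3O3S")
  expect_equal(unclass(f5)[c("C", "H", "N", "O", "S")],
               c(C = 12L, H = 13L, N = 3L, O = 3L, S = 1L))
  expect_identical(format_formula(parse_formula("")), "")
  expect_error(parse_formula("C9X2"), "unknown element")
  expect_error(parse_formula("9C"), "malformed")
  expect_error(as_formula(c(C = -1)), "negative")
})

test_that("parse/format round-trips over random CHNOS formulas", {
  set.seed(101)
  for (i in 1:500) {
    f <- random_formula()
    expect_true(parse_formula(format_formula(f)) == f)
  }
})

test_that("monoisotopic mass is the lightest-isotope atom sum and is additive", {
  expect_identical(monoisotopic_mass(""), 0)
  # hand sum from the pinned table: 9*12 + 10*1.00782503207
  #   + 2*14.00307401 + 31.97207100
  expect_equal(monoisotopic_mass("C9H10N2S"), 178.05646934, tolerance = 5e-7)
  set.seed(7)
  for (i in 1:50) {
    a <- random_formula(); b <- random_formula()
    ab <- apply_delta(a, add = b)
    expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
                 monoisotopic_mass(ab), tolerance = 1e-10)
  }
})

test_that("protonated m/z reproduces the published precursor values", {
  expect_equal(protonated_mz("C9H10N2S"), 179.0638, tolerance = 0.001)
  expect_equal(protonated_mz("C9H10N2O4S2"), 275.0155, tolerance = 0.001)
  expect_equal(protonated_mz("C15H18N2O7S"), 371.0908, tolerance = 0.001)
})

test_that("apply_delta performs elementwise arithmetic and flags infeasible removals", {
  expect_true(apply_delta("C9H10N2S", add = "O") ==
                parse_formula("C9H10N2OS"))
  expect_true(apply_delta("C9H10N2S", remove = "C2H4") ==
                parse_formula("C7H6N2S"))
  expect_error(apply_delta("C7H6N2S", remove = "O"),
               class = "bemetab_infeasible")
})

test_that("RDBE follows C - H/2 + N/2 + 1", {
  expect_equal(rdbe("C9H10N2S"), 6)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
})

test_that("ion m/z conventions differ by the electron and proton masses", {
  m <- monoisotopic_mass("C7H6N2S")
  expect_equal(ion_mz("C7H6N2S", "cation"), m - ELECTRON_MASS)
  expect_equal(ion_mz("C7H6N2S", "as-written"), m)
  expect_equal(ion_mz("C7H6N2S", "protonated"), m + PROTON_MASS)
  # the two routes to [M+H]+ agree: atom-sum of M+H minus electron vs
  # neutral mass plus proton
  expect_equal(ion_mz(apply_delta("C9H10N2S", add = "H"), "cation"),
               protonated_mz("C9H10N2S"), tolerance = 1e-7)
})
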