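test_that("peak tables validate their schema and precursor uniqueness", {
  fx <- load_paper_fixtures()
  expect_s3_class(fx$peaks, "peak_table")
  expect_identical(attr(fx$peaks, "provenance"), "paper-transcribed")
  pre <- fx$peaks[fx$peaks$role == "precursor", ]
  expect_identical(nrow(pre), 10L)  # parent + nine metabolite peaks

  dup <- rbind(pre[1, ], pre[1, ])
  expect_error(peak_table(dup), class = "bemetab_input")
  bad <- pre; bad$mz[1] <- -1
  expect_error(peak_table(bad), class = "bemetab_input")
  expect_error(peak_table(data.frame(x = 1)), class = "bemetab_input")
})

test_that("precursor matching assigns formulas within tolerance", {
  fx <- load_paper_fixtures()
  g <- expand_metabolites(bemethyl_root(), max_depth = 5)
  m <- match_precursors(fx$peaks, g, tol_ppm = 5)
  assigned <- table2_assigned()
  for (i in seq_len(nrow(assigned))) {
    row <- m[m$compound == assigned$compound[i], ]
    expect_identical(row$formula, assigned$formula[i],
                     info = assigned$compound[i])
    expect_true(row$matched)
    expect_lt(abs(row$ppm), 5)
    expect_identical(row$interpretation, "protonated")
  }
})

test_that("the anomalous M5 precursor is retained only by curated override", {
  fx <- load_paper_fixtures()
  g <- expand_metabolites(bemethyl_root(), max_depth = 5)
  m5 <- match_precursors(fx$peaks, g)[
    match_precursors(fx$peaks, g)$compound == "M5", ]
  expect_true(m5$matched)
  expect_identical(m5$interpretation, "curated-override")
  expect_identical(m5$formula, "C12H13N3O3S")
  expect_equal(m5$ppm, -21.9, tolerance = 0.1)

  # without the override the peak is reported unmatched with its best ppm
  m5b <- match_precursors(fx$peaks, g, curated = NULL)
  m5b <- m5b[m5b$compound == "M5", ]
  expect_false(m5b$matched)
  expect_true(is.na(m5b$interpretation))
})

test_that("absurd peaks stay unmatched and empty tables give empty results", {
  g <- expand_metabolites(bemethyl_root(), max_depth = 2)
  t0 <- peak_table(data.frame(role = "precursor", compound = "x",
                              rt_min = 1, mz = 50.0))
  m <- match_precursors(t0, g)
  expect_false(m$matched)
  expect_true(abs(m$ppm) > 5)

  empty <- peak_table(data.frame(role = character(), compound = character(),
                                 rt_min = numeric(), mz = numeric()))
  expect_identical(nrow(match_precursors(empty, g)), 0L)
})

test_that("product ions get precursor sub-formulas and neutral-loss labels", {
  ann <- annotate_product_ions(c(151.0324, 118.0531), "C9H10N2S")
  expect_identical(ann$ion_formula, c("C7H7N2S", "C7H6N2"))
  expect_identical(ann$loss_formula[1], "C2H4")
  expect_identical(ann$loss_label[1], "ethene")

  m6 <- annotate_product_ions(c(195.0587, 167.0274), "C15H18N2O7S")
  expect_identical(m6$ion_formula[1], "C9H11N2OS")
  expect_identical(m6$loss_formula[1], "C6H8O6")
  expect_identical(m6$loss_label[1], "glucuronyl")

  expect_identical(nrow(annotate_product_ions(numeric(), "C9H10N2S")), 0L)
  expect_error(annotate_product_ions(400.2, "C9H10N2S"), "heavier")
})

test_that("every transcribed product ion reproduces its printed formula", {
  fx <- load_paper_fixtures()
  curated <- curated_assignments()
  assigned <- rbind(table2_assigned(),
                    data.frame(compound = "M5", mz = curated$mz,
                               formula = curated$formula))
  for (i in seq_len(nrow(assigned))) {
    cmp <- assigned$compound[i]
    prods <- fx$peaks[fx$peaks$role == "product" &
                        fx$peaks$parent_compound == cmp, ]
    if (!nrow(prods)) next
    ann <- annotate_product_ions(prods, assigned$formula[i])
    expect_true(all(ann$matched), info = cmp)
    # the printed column sometimes omits the charging proton; the assigned
    # atomic composition must equal the printed one or printed + H
    for (j in seq_len(nrow(prods))) {
      printed <- as_formula(prods$printed_formula[j])
      got <- as_formula(ann$ion_formula[j])
      ok <- got == printed || got == apply_delta(printed, add = "H")
      expect_true(ok, info = paste(cmp, prods$mz[j]))
    }
  }
})

test_that("printed precursor masses agree with theory except M5", {
  fx <- load_paper_fixtures()
  assigned <- table2_assigned()
  ppm <- ppm_error(assigned$mz,
                   vapply(assigned$formula, protonated_mz, numeric(1)))
  expect_true(all(abs(ppm) < 5))
  m5_ppm <- ppm_error(280.0689, protonated_mz("C12H13N3O3S"))
  expect_equal(abs(m5_ppm), 22, tolerance = 1)
})

test_that("species accounting splits tautomers by RT and excludes the parent", {
  fx <- load_paper_fixtures()
  g <- expand_metabolites(bemethyl_root(), max_depth = 5)
  m <- match_precursors(fx$peaks, g)
  rep <- count_species(m)
  expect_identical(rep$species_count, 9L)
  expect_identical(rep$unique_formula_count, 6L)
  expect_identical(rep$parent$compound, "bemethyl")

  # invariance under row permutation
  set.seed(5)
  rep2 <- count_species(m[sample(nrow(m)), ])
  expect_identical(rep2$species_count, rep$species_count)
  expect_setequal(rep2$species$label, rep$species$label)

  single <- count_species(m[m$compound == "M4", ])
  expect_identical(single$species_count, 1L)
  expect_identical(single$unique_formula_count, 1L)
})
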