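test_that("simulation is reproducible per seed", {
  spec <- table2_ground_truth()
  a <- simulate_run(spec, seed = 4)
  b <- simulate_run(spec, seed = 4)
  expect_identical(a$traces, b$traces)
  expect_identical(a$peak_table, b$peak_table)
  c_ <- simulate_run(spec, seed = 5)
  expect_false(identical(a$traces, c_$traces))
})

test_that("peak integration recovers closed-form areas", {
  tm <- seq(0, 15, by = 0.01)
  gauss <- data.frame(time = tm, intensity = dnorm(tm, 7.5, 0.05))
  expect_equal(integrate_peak(gauss, c(7.0, 8.0)), 1.0, tolerance = 1e-3)
  expect_equal(integrate_peak(gauss, c(7.5 - 6 * 0.05, 7.5)), 0.5,
               tolerance = 1e-2)
  set.seed(2)
  flat <- data.frame(time = tm, intensity = rnorm(length(tm), 0, 0.01))
  expect_lt(abs(integrate_peak(flat, c(5, 6))), 0.01)
  expect_error(integrate_peak(gauss, c(14, 16)), "outside")
})

test_that("noiseless tautomer peaks recover the 60:1 area ratio exactly", {
  spec <- table2_ground_truth()
  spec$noise_sd_frac <- 0
  spec$mz_jitter_ppm <- 1e-12
  run <- simulate_run(spec, seed = 1)
  expect_equal(run$areas[["M1a"]] / run$areas[["M1b"]], 60,
               tolerance = 1e-3)
})

test_that("area ratios are recovered under default noise", {
  run1 <- simulate_run(table2_ground_truth(), seed = 1)
  expect_equal(run1$areas[["M1a"]] / run1$areas[["M1b"]], 60,
               tolerance = 0.10)
  ratios <- vapply(1:20, function(s) {
    a <- simulate_run(table2_ground_truth(), seed = s)$areas
    c(a[["M1a"]] / a[["M1b"]], a[["M2a"]] / a[["M2b"]],
      a[["M3-2"]] / a[["M3-1"]])
  }, numeric(3))
  med <- apply(ratios, 1, median)
  expect_equal(med, c(60, 40, 10), tolerance = 0.05)
})

test_that("an empty species list yields a flat noise trace", {
  spec <- chromatogram_spec(
    data.frame(label = character(), formula = character(),
               rt_min = numeric(), area = numeric()))
  run <- simulate_run(spec, seed = 1)
  expect_named(run$traces, "baseline")
  expect_identical(nrow(run$peak_table), 0L)
})

test_that("packaged fixtures load, are checksummed, and carry the printed values", {
  fx <- load_paper_fixtures()
  pre <- fx$peaks[fx$peaks$role == "precursor", ]
  expect_identical(sum(pre$compound != "bemethyl"), 9L)
  expect_equal(fx$scores$score[fx$scores$from == "bemethyl" &
                                 fx$scores$to == "M2a"], 4.20)
  expect_identical(fx$acquisition$nce_pct[fx$acquisition$compound == "M1"],
                   55L)

  # a tampered copy is refused
  d <- tempdir()
  tampered <- file.path(d, "fixcopy")
  dir.create(tampered, showWarnings = FALSE)
  for (nm in c("peaks_table2.csv", "acquisition_table3.csv",
               "pathway_scores.csv", "parent_formulas.csv")) {
    file.copy(fixture_path(nm), file.path(tampered, nm), overwrite = TRUE)
  }
  lines <- readLines(file.path(tampered, "pathway_scores.csv"))
  lines[2] <- sub("4.20", "9.99", lines[2], fixed = TRUE)
  writeLines(lines, file.path(tampered, "pathway_scores.csv"))
  expect_error(load_paper_fixtures(dir = tampered),
               class = "bemetab_corrupt_fixture")
  expect_silent(load_paper_fixtures(check = FALSE, dir = tampered))
})
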