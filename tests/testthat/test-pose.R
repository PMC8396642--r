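test_that("atom distances follow Euclid and are symmetric", {
  expect_equal(atom_distance(c(0, 0, 0), c(3, 0, 0)), 3)
  expect_equal(atom_distance(c(1, 2, 2), c(0, 0, 0)), 3)
  a <- c(1.2, -0.4, 7.7); b <- c(-2.2, 3.1, 0.5)
  expect_equal(atom_distance(a, b), atom_distance(b, a))
})

test_that("pose fixtures round-trip the requested separation", {
  for (d in c(3.65, 3.83, 4.00, 5.72)) {
    f <- tempfile(fileext = ".pdb")
    make_pose_fixture(f, d, seed = 42)
    p <- read_pose(f)
    expect_equal(atom_distance(p$donor, p$acceptors[[1]]), d,
                 tolerance = 1e-6)
  }
})

test_that("fixture generation is byte-identical for a fixed seed", {
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  make_pose_fixture(f1, 3.65, seed = 9)
  make_pose_fixture(f2, 3.65, seed = 9)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".pdb")
  make_pose_fixture(f3, 3.65, seed = 10)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("selectors must match exactly one atom and files must parse", {
  f <- tempfile(fileext = ".pdb")
  make_pose_fixture(f, 4.5, seed = 1)
  expect_error(read_pose(f, donor = "GSH:XX"), "matches 0")
  # duplicate the SG record to force an ambiguous selector
  lines <- readLines(f)
  sg <- grep("SG", lines, value = TRUE)
  dup <- sub("^HETATM    2", "HETATM    9", sg)
  writeLines(append(lines, dup, after = length(lines) - 1L), f)
  expect_error(read_pose(f), "matches 2")

  empty <- tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(read_pose(empty), class = "bemetab_input")
})

test_that("the published distances classify as in the docking analysis", {
  verdict_at <- function(d) {
    f <- tempfile(fileext = ".pdb")
    make_pose_fixture(f, d, seed = 3)
    assess_conjugation(read_pose(f))$verdict
  }
  # parent drug: 5.72 A, out of nucleophilic-attack reach
  expect_identical(verdict_at(5.72), "nonreactive")
  # sulfoxide and sulfone: within reach
  expect_identical(verdict_at(3.65), "reactive")
  expect_identical(verdict_at(3.83), "reactive")
  # the threshold itself is reactive (inclusive)
  expect_identical(verdict_at(4.00), "reactive")
  # vinyl-intermediate distances both exceed the threshold
  expect_identical(verdict_at(4.59), "nonreactive")
  expect_identical(verdict_at(4.03), "nonreactive")
})

test_that("multiple acceptors report per-atom distances and use the minimum", {
  f <- tempfile(fileext = ".pdb")
  make_pose_fixture(f, 4.59, seed = 12)
  p <- read_pose(f, acceptors = c("LIG:C2", "LIG:N1"))
  a <- assess_conjugation(p)
  expect_length(a$distances, 2L)
  expect_equal(a$dist_s_c2, min(a$distances))
})

test_that("distS-C2 is invariant under rigid motion and verdicts are monotone", {
  set.seed(77)
  xyz <- matrix(rnorm(6, sd = 5), nrow = 2)
  d0 <- atom_distance(xyz[1, ], xyz[2, ])
  for (i in 1:20) {
    moved <- random_rigid_transform(xyz)
    expect_equal(atom_distance(moved[1, ], moved[2, ]), d0,
                 tolerance = 1e-9)
  }
  verdicts <- vapply(sort(runif(10, 2, 6)), function(d) {
    f <- tempfile(fileext = ".pdb")
    make_pose_fixture(f, round(d, 3), seed = 1)
    assess_conjugation(read_pose(f))$verdict
  }, character(1))
  # once nonreactive, never reactive again as distance grows
  expect_true(all(diff(verdicts == "reactive") <= 0))
})
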