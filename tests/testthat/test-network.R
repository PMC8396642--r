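rule_by_name <- function(name) {
  rules <- bemethyl_rules()
  rules[[which(vapply(rules, `[[`, character(1), "name") == name)]]
}

test_that("the mercapturic-acid chain conserves elemental bookkeeping", {
  step <- function(f, rule) apply_delta(f, rule$add, rule$remove)
  t3 <- step(as_formula("C9H10N2OS"), rule_by_name("glutathione conjugation"))
  expect_identical(format_formula(t3), "C17H21N5O6S")
  cg <- step(t3, rule_by_name("gamma-glutamyl removal"))
  expect_identical(format_formula(cg), "C12H14N4O3S")
  cys <- step(cg, rule_by_name("cysteinylglycine cleavage"))
  expect_identical(format_formula(cys), "C10H11N3O2S")
  m5 <- step(cys, rule_by_name("N-acetylation"))
  expect_identical(format_formula(m5), "C12H13N3O3S")
})

test_that("expansion generates the observed metabolite formulas", {
  g1 <- expand_metabolites(bemethyl_root(),
                           list(rule_by_name("S-oxidation")), max_depth = 1)
  expect_true("C9H10N2OS" %in% g1$nodes$formula)
  expect_identical(nrow(g1$nodes), 2L)

  g0 <- expand_metabolites(bemethyl_root(), list(), max_depth = 3)
  expect_identical(nrow(g0$nodes), 1L)
  expect_identical(nrow(g0$edges), 0L)

  g <- expand_metabolites(bemethyl_root(), max_depth = 5)
  table2 <- c("C7H6N2S", "C9H10N2OS", "C9H10N2O3S", "C9H10N2O4S2",
              "C12H13N3O3S", "C15H18N2O7S")
  expect_true(all(table2 %in% g$nodes$formula))
})

test_that("expansion is deterministic and idempotent", {
  a <- expand_metabolites(bemethyl_root(), max_depth = 3)
  b <- expand_metabolites(bemethyl_root(), max_depth = 3)
  expect_identical(a, b)
})

test_that("path enumeration over the scored graph matches the published routes", {
  g <- bemethyl_score_graph()
  p3b <- enumerate_paths(g, "M3b")
  expect_length(p3b, 3L)
  p3a <- enumerate_paths(g, "M3a")
  expect_length(p3a, 1L)
  expect_identical(attr(p3a[[1]], "nodes"),
                   c("bemethyl", "M2b", "C16", "M3a"))
  root <- enumerate_paths(g, "bemethyl")
  expect_length(root, 1L)
  expect_identical(nrow(root[[1]]), 0L)
  expect_error(enumerate_paths(g, "M99"), "matches 0")
})

test_that("unreachable targets give an empty path list and zero score", {
  g <- bemethyl_score_graph()
  # orphan node: present but with no in-edges from the root side
  g$nodes <- rbind(g$nodes, data.frame(id = "orphan", label = "orphan",
                                       formula = "CH4", tags = "",
                                       depth = NA_integer_))
  expect_length(enumerate_paths(g, "orphan"), 0L)
  expect_identical(metabolite_total_score(g, "orphan"), 0)
})

test_that("path scores multiply and totals sum to the published values", {
  expect_equal(round(path_score(c(2.49, 2.15, 1.81)), 2), 9.69)
  expect_equal(round(path_score(c(4.20, 4.14, 2.52)), 2), 43.82)
  expect_equal(path_score(3.3), 3.3)
  expect_error(path_score(c(2.49, NA)), class = "bemetab_unscorable")

  g <- bemethyl_score_graph()
  m3a <- metabolite_total_score(g, "M3a")
  m3b <- metabolite_total_score(g, "M3b")
  expect_equal(round(m3a, 2), 9.69)
  expect_equal(round(m3b, 2), 107.99)
  # the sulfone route dominates the triple ring oxidation
  expect_gt(m3b / m3a, 1)
})

test_that("graph exports carry labels, formulas and scores", {
  g <- bemethyl_score_graph()
  el <- graph_edge_list(g)
  expect_true(all(c("from", "to", "rule", "score") %in% names(el)))
  expect_equal(el$score[el$from == "bemethyl" & el$to == "M2a"], 4.20)
  dot <- graph_to_dot(g)
  expect_match(dot, "digraph")
  expect_match(dot, "\"bemethyl\" -> \"M2a\"", fixed = TRUE)
  f <- tempfile(fileext = ".csv")
  graph_edge_list(g, f)
  expect_identical(nrow(utils::read.csv(f)), nrow(g$edges))
})

test_that("a score table without a unique root is rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("from,from_formula,to,to_formula,rule,score",
               "a,CH4,b,CH4O,oxidation,1.0",
               "c,C2H6,d,C2H6O,oxidation,2.0"), f)
  expect_error(bemethyl_score_graph(f), "exactly one root")
})
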