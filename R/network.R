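#' Biotransformation rules
#'
#' A rule is a formula delta (atoms added, atoms removed) guarded by
#' functional-group tags: it applies to a metabolite node only when the node
#' carries every `requires` tag; on application it removes the `consumes`
#' tags and adds the `produces` tags. Rules carry the catalysing enzyme
#' labels and the metabolism phase (I: oxidation/dealkylation; II:
#' conjugation). Working at (formula, tag) level rather than on molecular
#' graphs matches how the metabolite assignments themselves are made: the
#' precise position of, say, a ring hydroxyl is not determined by the mass
#' spectra, but its presence gates sulfation and glucuronidation.
#'
#' @param name Rule name.
#' @param add,remove Formula deltas (strings; `""` for none).
#' @param requires,consumes,produces Character vectors of group tags.
#' @param enzymes Free-text enzyme labels.
#' @param phase `"I"` or `"II"`.
#' @export
transformation_rule <- function(name, add = "", remove = "",
                                requires = character(), consumes = character(),
                                produces = character(), enzymes = "",
                                phase = c("I", "II")) {
  phase <- match.arg(phase)
  # validate deltas eagerly
  as_formula(add); as_formula(remove)
  structure(list(name = name, add = add, remove = remove,
                 requires = requires, consumes = consumes,
                 produces = produces, enzymes = enzymes, phase = phase),
            class = "transformation_rule")
}

#' A node of the metabolite graph
#'
#' @param label Display label (`"bemethyl"`, `"M2a"`, ... or generated).
#' @param formula Neutral formula (string or `chem_formula`).
#' @param tags Character vector of functional-group tags.
#' @export
metabolite_node <- function(label, formula, tags = character()) {
  structure(list(label = label, formula = as_formula(formula),
                 tags = sort(unique(tags))),
            class = "metabolite_node")
}

#' The parent drug as the root node
#'
#' Bemethyl, 2-(ethylthio)benzimidazole, C9H10N2S: an aromatic
#' benzimidazole core (hydroxylatable CH positions), an S-ethyl thioether
#' (oxidisable sulfur), and an aliphatic ethyl (alpha-carbon
#' hydroxylatable).
#'
#' @export
bemethyl_root <- function() {
  metabolite_node("bemethyl", "C9H10N2S",
                  c("thioether", "aromatic-CH", "aliphatic-CH"))
}

#' The packaged bemethyl rule set
#'
#' The phase I oxidations and phase II conjugations that generate the
#' observed urinary metabolites of bemethyl:
#' sulfur oxidation to sulfoxide and on to sulfone (CYP), aromatic ring
#' hydroxylation (CYP), alpha-carbon hydroxylation of the S-ethyl followed
#' by oxidative S-de-ethylation (yielding 2-thiobenzimidazole), sulfation
#' (SULT/PAPS) and glucuronidation (UGT) of a ring hydroxyl, and the
#' mercapturic-acid chain: glutathione displacement of the ethylsulfinyl
#' group (GST, requires the sulfoxide), gamma-glutamyl removal (GGT),
#' cysteinylglycine cleavage (CGDP) and N-acetylation (NAT) to the stable
#' N-acetylcysteine conjugate.
#'
#' @return List of [transformation_rule()] objects.
#' @export
bemethyl_rules <- function() {
  list(
    transformation_rule("S-oxidation", add = "O",
      requires = "thioether", consumes = "thioether", produces = "sulfoxide",
      enzymes = "CYP1A2, CYP2A6, CYP2B6, CYP2C9, CYP3A4", phase = "I"),
    transformation_rule("sulfoxide oxidation", add = "O",
      requires = "sulfoxide", consumes = "sulfoxide", produces = "sulfone",
      enzymes = "CYP2C9, CYP3A4", phase = "I"),
    transformation_rule("aromatic hydroxylation", add = "O",
      requires = "aromatic-CH", produces = "aromatic-OH",
      enzymes = "CYP1A2, CYP2A6, CYP2B6, CYP2C9, CYP2C19, CYP3A4",
      phase = "I"),
    transformation_rule("alpha-carbon hydroxylation", add = "O",
      requires = "aliphatic-CH", consumes = "aliphatic-CH",
      produces = "aliphatic-OH", enzymes = "CYP (subtype undetermined)",
      phase = "I"),
    transformation_rule("oxidative S-de-ethylation", remove = "C2H4O",
      requires = "aliphatic-OH", consumes = "aliphatic-OH",
      produces = "thiol-thione", enzymes = "CYP (subtype undetermined)",
      phase = "I"),
    transformation_rule("sulfation", add = "SO3",
      requires = "aromatic-OH", consumes = "aromatic-OH",
      produces = "sulfate-ester", enzymes = "SULT (PAPS cofactor)",
      phase = "II"),
    transformation_rule("glucuronidation", add = "C6H8O6",
      requires = "aromatic-OH", consumes = "aromatic-OH",
      produces = "glucuronide", enzymes = "UGT (UDP-Gluc cofactor)",
      phase = "II"),
    transformation_rule("glutathione conjugation", add = "C10H17N3O6S",
      remove = "C2H6OS",
      requires = "sulfoxide", consumes = c("sulfoxide", "aliphatic-CH"),
      produces = "SG-conjugate", enzymes = "GST", phase = "II"),
    transformation_rule("gamma-glutamyl removal", remove = "C5H7NO3",
      requires = "SG-conjugate", consumes = "SG-conjugate",
      produces = "cysgly-conjugate", enzymes = "GGT", phase = "II"),
    transformation_rule("cysteinylglycine cleavage", remove = "C2H3NO",
      requires = "cysgly-conjugate", consumes = "cysgly-conjugate",
      produces = "cys-conjugate", enzymes = "CGDP", phase = "II"),
    transformation_rule("N-acetylation", add = "C2H2O",
      requires = "cys-conjugate", consumes = "cys-conjugate",
      produces = "nac-conjugate", enzymes = "NAT", phase = "II")
  )
}

.node_key <- function(formula, tags) {
  paste0(format_formula(formula), "|", paste(sort(tags), collapse = ","))
}

.new_graph <- function(nodes, edges, root_id) {
  structure(list(nodes = nodes, edges = edges, root = root_id),
            class = "metabolite_graph")
}

#' Expand a metabolite graph from a root by rule application
#'
#' Breadth-first application of every feasible rule, deduplicating nodes by
#' (formula, tag set), to at most `max_depth` transformations from the
#' root. Infeasible rules (missing tag, or a delta that would remove atoms
#' the formula lacks) are skipped. The result is a DAG rooted at the parent
#' drug. Deterministic for fixed inputs.
#'
#' @param root A [metabolite_node()].
#' @param rules List of [transformation_rule()] (default the packaged set).
#' @param max_depth Maximum number of transformations (>= 0).
#' @return A `metabolite_graph`: list with `nodes` (data.frame: `id`,
#'   `label`, `formula`, `tags`, `depth`), `edges` (data.frame: `from`,
#'   `to`, `rule`, `enzymes`, `phase`, `score` — scores `NA` here; see
#'   [bemethyl_score_graph()] for the scored pathway graph), `root`.
#' @examples
#' g <- expand_metabolites(bemethyl_root(), max_depth = 2)
#' "C9H10N2OS" %in% g$nodes$formula  # sulfoxide / hydroxide generation
#' @export
expand_metabolites <- function(root, rules = bemethyl_rules(), max_depth = 3L) {
  stopifnot(inherits(root, "metabolite_node"), max_depth >= 0L)
  keys <- .node_key(root$formula, root$tags)
  nodes <- data.frame(id = "n1", label = root$label,
                      formula = format_formula(root$formula),
                      tags = paste(root$tags, collapse = ";"),
                      depth = 0L, stringsAsFactors = FALSE)
  tagsets <- list(root$tags)
  edges <- data.frame(from = character(), to = character(),
                      rule = character(), enzymes = character(),
                      phase = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  frontier <- 1L
  depth <- 0L
  while (length(frontier) && depth < max_depth) {
    depth <- depth + 1L
    next_frontier <- integer()
    for (i in frontier) {
      tags_i <- tagsets[[i]]
      f_i <- as_formula(nodes$formula[i])
      for (rule in rules) {
        if (!all(rule$requires %in% tags_i)) next
        f_new <- tryCatch(apply_delta(f_i, rule$add, rule$remove),
                          bemetab_infeasible = function(e) NULL)
        if (is.null(f_new)) next
        tags_new <- sort(unique(c(setdiff(tags_i, rule$consumes),
                                  rule$produces)))
        key <- .node_key(f_new, tags_new)
        j <- match(key, keys)
        if (is.na(j)) {
          j <- length(keys) + 1L
          keys[j] <- key
          nodes <- rbind(nodes, data.frame(
            id = paste0("n", j), label = paste0("n", j),
            formula = format_formula(f_new),
            tags = paste(tags_new, collapse = ";"),
            depth = depth, stringsAsFactors = FALSE))
          tagsets[[j]] <- tags_new
          next_frontier <- c(next_frontier, j)
        }
        # record the edge (dedup parallel edges by from/to/rule)
        dup <- edges$from == nodes$id[i] & edges$to == nodes$id[j] &
          edges$rule == rule$name
        if (!any(dup)) {
          edges <- rbind(edges, data.frame(
            from = nodes$id[i], to = nodes$id[j], rule = rule$name,
            enzymes = rule$enzymes, phase = rule$phase, score = NA_real_,
            stringsAsFactors = FALSE))
        }
      }
    }
    frontier <- next_frontier
  }
  .new_graph(nodes, edges, "n1")
}

#' @export
print.metabolite_graph <- function(x, ...) {
  cat("<metabolite_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, root ", x$nodes$label[x$nodes$id == x$root], "\n", sep = "")
  invisible(x)
}

.resolve_node <- function(g, node) {
  hit <- which(g$nodes$id == node | g$nodes$label == node)
  if (length(hit) != 1L) {
    stop("node '", node, "' matches ", length(hit), " graph nodes; known ",
         "labels: ", paste(g$nodes$label, collapse = ", "), call. = FALSE)
  }
  g$nodes$id[hit]
}

#' Enumerate all simple root-to-target pathways
#'
#' Depth-first enumeration of every simple directed path from the graph
#' root to `target`, in deterministic order (lexicographic by the node
#' labels along the path). The zero-length path is returned when the target
#' is the root; an unreachable target gives an empty list.
#'
#' @param g A `metabolite_graph`.
#' @param target Node id or label.
#' @return List of paths; each path is a data.frame of the edges traversed
#'   (zero rows for the root itself), with a `nodes` attribute holding the
#'   node labels visited.
#' @export
enumerate_paths <- function(g, target) {
  tid <- .resolve_node(g, target)
  label_of <- stats::setNames(g$nodes$label, g$nodes$id)
  paths <- list()
  walk <- function(at, edge_idx, visited) {
    if (at == tid) {
      p <- g$edges[edge_idx, , drop = FALSE]
      rownames(p) <- NULL
      attr(p, "nodes") <- unname(label_of[c(visited, at)])
      paths[[length(paths) + 1L]] <<- p
      return(invisible())
    }
    out <- which(g$edges$from == at & !(g$edges$to %in% c(visited, at)))
    # deterministic order: by label of the child node
    out <- out[order(label_of[g$edges$to[out]])]
    for (e in out) walk(g$edges$to[e], c(edge_idx, e), c(visited, at))
  }
  walk(g$root, integer(), character())
  paths
}

#' Pathway probability score
#'
#' Treating the per-step metabolite scores as probabilities, the score of a
#' pathway is the product of its edge scores. A missing score on any edge
#' makes the path unscorable (error of class `bemetab_unscorable`).
#'
#' @param path A data.frame of edges with a `score` column (as returned in
#'   [enumerate_paths()]), or a bare numeric vector of edge scores.
#' @return The product of the edge scores (1 for a zero-length path).
#' @examples
#' path_score(c(2.49, 2.15, 1.81))  # 9.69 at 2 dp
#' @export
path_score <- function(path) {
  scores <- if (is.data.frame(path)) path$score else as.numeric(path)
  if (anyNA(scores)) {
    stop(structure(class = c("bemetab_unscorable", "error", "condition"),
                   list(message = "unscorable path: edge without a score",
                        call = sys.call(-1))))
  }
  prod(scores)
}

#' Total pathway score of a metabolite
#'
#' Sum over all simple root-to-target pathways of the per-pathway products
#' of edge scores. This is the aggregation under which the triple-oxidation
#' route to M3 scores 9.69 while the sulfone route scores 107.99, the basis
#' for reading the M3 signal as predominantly the hydroxylated sulfone.
#'
#' @param g A scored `metabolite_graph` (see [bemethyl_score_graph()]).
#' @param target Node id or label.
#' @return Sum of path products; 0 when the target is unreachable.
#' @export
metabolite_total_score <- function(g, target) {
  paths <- enumerate_paths(g, target)
  if (!length(paths)) return(0)
  sum(vapply(paths, path_score, numeric(1)))
}

#' Export a metabolite graph
#'
#' `graph_edge_list()` returns (and optionally writes) the edge list with
#' node labels and formulas resolved; `graph_to_dot()` renders Graphviz DOT
#' for visualisation.
#'
#' @param g A `metabolite_graph`.
#' @param file Optional path; CSV for the edge list, DOT text otherwise.
#' @export
graph_edge_list <- function(g, file = NULL) {
  lab <- stats::setNames(g$nodes$label, g$nodes$id)
  fml <- stats::setNames(g$nodes$formula, g$nodes$id)
  out <- data.frame(from = unname(lab[g$edges$from]),
                    from_formula = unname(fml[g$edges$from]),
                    to = unname(lab[g$edges$to]),
                    to_formula = unname(fml[g$edges$to]),
                    rule = g$edges$rule, enzymes = g$edges$enzymes,
                    phase = g$edges$phase, score = g$edges$score,
                    stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @rdname graph_edge_list
#' @export
graph_to_dot <- function(g, file = NULL) {
  lab <- stats::setNames(g$nodes$label, g$nodes$id)
  lines <- c("digraph metabolites {",
             sprintf('  "%s" [label="%s\\n%s"];', g$nodes$label,
                     g$nodes$label, g$nodes$formula),
             sprintf('  "%s" -> "%s" [label="%s"];',
                     lab[g$edges$from], lab[g$edges$to],
                     ifelse(is.na(g$edges$score), g$edges$rule,
                            sprintf("%s (%.2f)", g$edges$rule,
                                    g$edges$score))),
             "}")
  if (!is.null(file)) writeLines(lines, file)
  invisible(paste(lines, collapse = "\n"))
}

#' The packaged scored oxidation-pathway graph
#'
#' The scored DAG of the first three oxidation generations of bemethyl,
#' with the published per-step metabolite scores attached to its edges.
#' Nodes are the parent, the first-generation oxidation products (the
#' sulfoxide M2a, the ring-hydroxylated M2b, the alpha-hydroxylated T1, and
#' the low-probability vinyl sulfide), the second-generation intermediates
#' (the sulfone T2 and the hydroxy-sulfoxides; the two hydroxy-sulfoxide
#' intermediates are kept as distinct nodes because their formation scores
#' depend on which oxidation came first), and the two candidate structures
#' for the triply oxygenated metabolite M3: the ring-trihydroxylated M3a
#' and the hydroxylated sulfone M3b.
#'
#' @param path CSV file with columns `from`, `from_formula`, `to`,
#'   `to_formula`, `rule`, `score`; defaults to the packaged score table.
#' @return A scored `metabolite_graph`.
#' @examples
#' g <- bemethyl_score_graph()
#' round(metabolite_total_score(g, "M3b"), 2)
#' @export
bemethyl_score_graph <- function(path = NULL) {
  if (is.null(path)) {
    path <- fixture_path("pathway_scores.csv")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from", "from_formula", "to", "to_formula", "rule", "score")
  if (!all(need %in% names(tab))) {
    stop("score table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  labs <- unique(c(tab$from, tab$to))
  fml <- character(length(labs)); names(fml) <- labs
  fml[tab$from] <- tab$from_formula
  fml[tab$to] <- tab$to_formula
  nodes <- data.frame(id = labs, label = labs, formula = unname(fml[labs]),
                      tags = "", depth = NA_integer_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = tab$from, to = tab$to, rule = tab$rule,
                      enzymes = if ("enzymes" %in% names(tab)) tab$enzymes
                                else "", phase = "I",
                      score = as.numeric(tab$score),
                      stringsAsFactors = FALSE)
  root <- setdiff(labs, tab$to)
  if (length(root) != 1L) {
    stop("score table must have exactly one root; found: ",
         paste(root, collapse = ", "), call. = FALSE)
  }
  .new_graph(nodes, edges, root)
}
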