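#' Pipeline configuration
#'
#' @param tol_ppm Precursor/product matching tolerance, ppm.
#' @param bounds [element_bounds()] for formula decomposition.
#' @param rt_split_min RT gap (min) separating species of equal formula.
#' @param pose_threshold Reactivity threshold, Angstrom.
#' @param max_depth Biotransformation expansion depth (5 reaches the full
#'   mercapturic-acid chain).
#' @param seed RNG seed for simulation stages.
#' @param out_dir Optional report output directory.
#' @export
pipeline_config <- function(tol_ppm = 5, bounds = element_bounds(),
                            rt_split_min = 0.5, pose_threshold = 4.0,
                            max_depth = 5L, seed = 1L, out_dir = NULL) {
  stopifnot(tol_ppm > 0, rt_split_min >= 0, pose_threshold > 0,
            max_depth >= 1L)
  structure(list(tol_ppm = tol_ppm, bounds = bounds,
                 rt_split_min = rt_split_min,
                 pose_threshold = pose_threshold,
                 max_depth = as.integer(max_depth), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Annotate a peak table end to end
#'
#' Expands the biotransformation network from the parent drug, matches
#' every precursor peak to a candidate formula, annotates product ions
#' with sub-formulas and neutral-loss labels, and counts metabolite
#' species and unique molecular formulas.
#'
#' @param peaks A [peak_table()], a data.frame in its schema, or a CSV
#'   path.
#' @param config A [pipeline_config()].
#' @return An `annotation_report`: list with `matches`, `products`,
#'   `species` (a `species_report`), `species_count`,
#'   `unique_formula_count`, `overrides`, `config`.
#' @examples
#' rep <- run_annotate(load_paper_fixtures()$peaks)
#' rep$species_count          # 9
#' rep$unique_formula_count   # 6
#' @export
run_annotate <- function(peaks, config = pipeline_config()) {
  pt <- if (inherits(peaks, "peak_table")) peaks
        else if (is.data.frame(peaks)) peak_table(peaks)
        else read_peak_table(peaks)
  graph <- expand_metabolites(bemethyl_root(), bemethyl_rules(),
                              max_depth = config$max_depth)
  matches <- match_precursors(pt, graph, tol_ppm = config$tol_ppm)
  prods <- list()
  for (i in seq_len(nrow(matches))) {
    if (!isTRUE(matches$matched[i])) next
    sub <- pt[pt$role == "product" &
                pt$parent_compound %in% matches$compound[i], , drop = FALSE]
    if (!nrow(sub)) next
    ann <- annotate_product_ions(sub, matches$formula[i],
                                 tol_ppm = config$tol_ppm)
    ann <- cbind(compound = matches$compound[i], ann)
    prods[[length(prods) + 1L]] <- ann
  }
  products <- if (length(prods)) do.call(rbind, prods) else
    data.frame(compound = character(), mz = numeric(),
               ion_formula = character())
  species <- count_species(matches, rt_split_min = config$rt_split_min)
  structure(list(matches = matches, products = products, species = species,
                 species_count = species$species_count,
                 unique_formula_count = species$unique_formula_count,
                 overrides = matches[matches$interpretation %in%
                                       "curated-override", , drop = FALSE],
                 config = config),
            class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("<annotation_report> ", nrow(x$matches), " precursors, ",
      x$species_count, " metabolite species, ",
      x$unique_formula_count, " unique formulas",
      if (nrow(x$overrides)) paste0(" (", nrow(x$overrides),
                                    " curated override)"), "\n", sep = "")
  invisible(x)
}

#' Score the pathways to a metabolite
#'
#' Enumerates the simple pathways from the parent to `target` in the
#' scored oxidation graph, reports the per-pathway product of edge scores
#' and their total.
#'
#' @param target Node label (e.g. `"M3a"`, `"M3b"`).
#' @param score_table Optional path to a score-table CSV; defaults to the
#'   packaged one.
#' @return A `score_report`: list with `target`, `paths` (data.frame:
#'   `route`, `score`), `total`.
#' @examples
#' run_score("M3b")$total  # 107.99 at 2 dp
#' @export
run_score <- function(target, score_table = NULL) {
  g <- bemethyl_score_graph(score_table)
  paths <- enumerate_paths(g, target)
  tab <- data.frame(
    route = vapply(paths, function(p)
      paste(attr(p, "nodes"), collapse = " -> "), character(1)),
    score = vapply(paths, path_score, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(target = target, paths = tab,
                 total = if (nrow(tab)) sum(tab$score) else 0),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> ", x$target, ": total ", sprintf("%.2f", x$total),
      " over ", nrow(x$paths), " pathway(s)\n", sep = "")
  for (i in seq_len(nrow(x$paths))) {
    cat(sprintf("  %7.2f  %s\n", x$paths$score[i], x$paths$route[i]))
  }
  invisible(x)
}

#' Screen docked poses for conjugation competence
#'
#' @param paths Character vector of PDB files.
#' @param donor,acceptors Atom selectors, see [read_pose()].
#' @param threshold Reactivity threshold, Angstrom.
#' @return A `pose_report`: list with `poses` (data.frame: `path`,
#'   `dist_s_c2`, `verdict`), `n_reactive`, `n_nonreactive`, `threshold`.
#' @export
run_pose <- function(paths, donor = "GSH:SG", acceptors = "LIG:C2",
                     threshold = 4.0) {
  rows <- lapply(paths, function(p) {
    a <- assess_conjugation(read_pose(p, donor, acceptors), threshold)
    data.frame(path = p, dist_s_c2 = a$dist_s_c2, verdict = a$verdict,
               stringsAsFactors = FALSE)
  })
  poses <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), dist_s_c2 = numeric(),
               verdict = character())
  structure(list(poses = poses,
                 n_reactive = sum(poses$verdict == "reactive"),
                 n_nonreactive = sum(poses$verdict == "nonreactive"),
                 threshold = threshold),
            class = "pose_report")
}

#' Write a report as JSON plus CSV tables
#'
#' @param report An `annotation_report`, `score_report` or `pose_report`.
#' @param dir Output directory (created if absent).
#' @param name Base file name (defaults to the report class).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir, name = class(report)[1]) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- Filter(is.data.frame, report)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(name, "_", nm,
                                                       ".csv")),
                     row.names = FALSE)
  }
  json <- file.path(dir, paste0(name, ".json"))
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1L,
                    unclass(report))
  payload <- c(scalars, lapply(tabs, function(d) d))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(json)
}
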