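#' Peak tables
#'
#' A `peak_table` is a data.frame of precursor and product ion peaks in the
#' schema of the packaged transcription: columns `role`
#' (`"precursor"`/`"product"`), `compound`, `rt_min`, `mz`,
#' `rel_intensity_pct`, `parent_compound`, and optional acquisition
#' metadata (`scan_range`, `nce_pct`) and `printed_formula`. Precursor
#' entries must be unique by (m/z to 4 dp, RT to 2 dp).
#'
#' @param x data.frame in the schema above, or a path for
#'   `read_peak_table()`.
#' @param provenance `"paper-transcribed"` or `"simulated"`.
#' @export
peak_table <- function(x, provenance = "simulated") {
  need <- c("role", "compound", "rt_min", "mz")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(structure(
      class = c("bemetab_input", "error", "condition"),
      list(message = paste0("peak table must have columns ",
                            paste(need, collapse = ", ")),
           call = sys.call(-1))))
  }
  x$mz <- as.numeric(x$mz); x$rt_min <- as.numeric(x$rt_min)
  if (anyNA(x$mz) || any(x$mz <= 0) || any(x$rt_min < 0, na.rm = TRUE)) {
    stop(structure(
      class = c("bemetab_input", "error", "condition"),
      list(message = "peak table m/z must be positive and RT non-negative",
           call = sys.call(-1))))
  }
  pre <- x[x$role == "precursor", ]
  key <- paste(round(pre$mz, 4), round(pre$rt_min, 2))
  if (anyDuplicated(key)) {
    stop(structure(
      class = c("bemetab_input", "error", "condition"),
      list(message = "duplicate precursor entries by (m/z, RT)",
           call = sys.call(-1))))
  }
  structure(x, class = c("peak_table", "data.frame"),
            provenance = provenance)
}

#' @rdname peak_table
#' @param path CSV file path.
#' @export
read_peak_table <- function(path, provenance = "paper-transcribed") {
  tab <- tryCatch(suppressWarnings(utils::read.csv(path,
                                                   stringsAsFactors = FALSE)),
                  error = function(e) {
                    stop(structure(
                      class = c("bemetab_input", "error", "condition"),
                      list(message = paste0("cannot read peak table '", path,
                                            "': ", conditionMessage(e)),
                           call = sys.call(-1))))
                  })
  peak_table(tab, provenance = provenance)
}

#' Curated precursor assignments
#'
#' Assignments retained although the printed precursor m/z is outside the
#' ppm tolerance of the theoretical value for the assigned formula. The one
#' such case in the bemethyl table is M5, the N-acetylcysteine conjugate:
#' the published precursor m/z 280.0689 sits about 22 ppm below the
#' theoretical protonated C12H13N3O3S (280.0750). The package reports the
#' discrepancy and keeps the assignment under a `curated-override` flag; it
#' does not silently correct either number.
#'
#' @return data.frame with columns `mz` (printed, 4 dp) and `formula`.
#' @export
curated_assignments <- function() {
  data.frame(mz = 280.0689, formula = "C12H13N3O3S",
             stringsAsFactors = FALSE)
}

.candidate_formulas <- function(candidates) {
  if (inherits(candidates, "metabolite_graph")) {
    unique(candidates$nodes$formula)
  } else {
    unique(vapply(candidates, function(f) format_formula(as_formula(f)),
                  character(1)))
  }
}

#' Match precursor peaks against candidate metabolite formulas
#'
#' Each precursor peak is assigned the candidate neutral formula whose
#' protonated m/z is closest in absolute ppm and within `tol_ppm`.
#' Unmatched peaks are reported with their best out-of-tolerance candidate
#' and its ppm error; a peak listed in the `curated` table is then retained
#' under the `curated-override` interpretation, with the computed
#' discrepancy preserved.
#'
#' @param t A [peak_table()].
#' @param candidates A `metabolite_graph` (its node formulas are the
#'   candidates) or a character vector of neutral formulas.
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @param curated Curated override table (see [curated_assignments()]);
#'   `NULL` to disable.
#' @return data.frame, one row per precursor: `compound`, `mz`, `rt_min`,
#'   `formula`, `theoretical_mz`, `ppm`, `matched`, `interpretation`
#'   (`"protonated"`, `"curated-override"`, or `NA`).
#' @export
match_precursors <- function(t, candidates, tol_ppm = 5,
                             curated = curated_assignments()) {
  stopifnot(tol_ppm > 0)
  pre <- t[t$role == "precursor", , drop = FALSE]
  fmls <- .candidate_formulas(candidates)
  theo <- vapply(fmls, protonated_mz, numeric(1))
  out <- lapply(seq_len(nrow(pre)), function(i) {
    mz <- pre$mz[i]
    ppm <- ppm_error(mz, theo)
    best <- order(abs(ppm))[1]
    row <- data.frame(compound = pre$compound[i], mz = mz,
                      rt_min = pre$rt_min[i], formula = fmls[best],
                      theoretical_mz = unname(theo[best]),
                      ppm = unname(ppm[best]),
                      matched = abs(ppm[best]) <= tol_ppm,
                      interpretation = NA_character_,
                      stringsAsFactors = FALSE)
    if (row$matched) {
      row$interpretation <- "protonated"
    } else if (!is.null(curated)) {
      hit <- which(round(curated$mz, 4) == round(mz, 4))
      if (length(hit) == 1L) {
        cf <- curated$formula[hit]
        row$formula <- cf
        row$theoretical_mz <- protonated_mz(cf)
        row$ppm <- ppm_error(mz, row$theoretical_mz)
        row$matched <- TRUE
        row$interpretation <- "curated-override"
      }
    }
    row
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(compound = character(), mz = numeric(),
                      rt_min = numeric(), formula = character(),
                      theoretical_mz = numeric(), ppm = numeric(),
                      matched = logical(), interpretation = character())
  }
  res
}

#' Packaged neutral-loss table
#'
#' The neutral fragments whose losses recur in the bemethyl metabolite
#' spectra: ethene (retro-S-ethylation), CO, water, sulfur monoxide and
#' trioxide (sulfoxide/sulfate chemistry), the glucuronyl moiety, and the
#' mercapturic-pathway residues (pyroglutamyl/glutamyl, glycyl as C2H3NO,
#' and the acetyl ketene).
#'
#' @return data.frame with columns `formula`, `label`, `mass`.
#' @export
neutral_loss_table <- function() {
  tab <- data.frame(
    formula = c("C2H4", "CO", "H2O", "SO", "SO3", "C6H8O6", "C5H7NO3",
                "C2H3NO", "C2H2O"),
    label = c("ethene", "carbon monoxide", "water", "sulfur monoxide",
              "sulfur trioxide", "glucuronyl", "glutamyl residue",
              "glycyl residue", "ketene (acetyl)"),
    stringsAsFactors = FALSE)
  tab$mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
  tab
}

# enumerate all non-empty elemental sub-formulas of a parent composition
.subformulas <- function(parent) {
  parent <- as_formula(parent)
  grids <- lapply(names(parent), function(el) 0:parent[[el]])
  names(grids) <- names(parent)
  g <- as.matrix(expand.grid(grids))
  g[rowSums(g) > 0L, , drop = FALSE]
}

#' Annotate the product ions of a matched precursor
#'
#' Each product-ion m/z is assigned the elemental sub-formula of the
#' precursor ion (neutral parent plus the charging proton) whose m/z is
#' closest within `tol_ppm`. Candidate m/z values are evaluated under the
#' even-electron cation convention (atom-mass sum minus one electron mass)
#' and, as a fallback, the plain atom-mass sum ("as-written"), because
#' published product-ion tables are not consistent about the electron; the
#' interpretation that matched is recorded per ion. The complementary
#' neutral loss is labelled from [neutral_loss_table()] when its formula is
#' listed there.
#'
#' @param products Numeric vector of product-ion m/z values, or a
#'   data.frame with columns `mz` and optionally `rel_intensity_pct`.
#' @param parent_formula Neutral formula of the precursor.
#' @param tol_ppm Tolerance in ppm.
#' @return data.frame: `mz`, `ion_formula` (assigned atomic composition of
#'   the ion), `theoretical_mz`, `ppm`, `interpretation`, `loss_formula`,
#'   `loss_label`, `matched`.
#' @examples
#' annotate_product_ions(c(151.0324, 93.0581, 118.0531), "C9H10N2S")
#' @export
annotate_product_ions <- function(products, parent_formula, tol_ppm = 5) {
  if (is.data.frame(products)) {
    mzs <- as.numeric(products$mz)
  } else {
    mzs <- as.numeric(products)
  }
  parent_ion <- apply_delta(as_formula(parent_formula), add = "H")
  parent_mz <- ion_mz(parent_ion, "cation")
  if (any(mzs > parent_mz + 0.01)) {
    stop("product ion heavier than its precursor (",
         max(mzs), " > ", round(parent_mz, 4), ")", call. = FALSE)
  }
  if (!length(mzs)) {
    return(data.frame(mz = numeric(), ion_formula = character(),
                      theoretical_mz = numeric(), ppm = numeric(),
                      interpretation = character(),
                      loss_formula = character(), loss_label = character(),
                      matched = logical()))
  }
  sub <- .subformulas(parent_ion)
  mono <- .mono_masses()[colnames(sub)]
  atom_sum <- drop(sub %*% mono)
  hetero <- rowSums(sub[, setdiff(colnames(sub), c("C", "H")), drop = FALSE])
  losses <- neutral_loss_table()

  rows <- lapply(mzs, function(mz) {
    pick <- NULL
    for (conv in c("cation", "as-written")) {
      theo <- if (conv == "cation") atom_sum - ELECTRON_MASS else atom_sum
      ppm <- ppm_error(mz, theo)
      ok <- which(abs(ppm) <= tol_ppm)
      if (length(ok)) {
        ok <- ok[order(abs(ppm[ok]), hetero[ok])]
        pick <- list(idx = ok[1], theo = theo[ok[1]], ppm = ppm[ok[1]],
                     conv = conv)
        break
      }
    }
    if (is.null(pick)) {
      return(data.frame(mz = mz, ion_formula = NA_character_,
                        theoretical_mz = NA_real_, ppm = NA_real_,
                        interpretation = NA_character_,
                        loss_formula = NA_character_,
                        loss_label = NA_character_, matched = FALSE,
                        stringsAsFactors = FALSE))
    }
    ionf <- as_formula(sub[pick$idx, ])
    loss <- apply_delta(parent_ion, remove = ionf)
    loss_str <- format_formula(loss)
    hit <- match(loss_str, losses$formula)
    data.frame(mz = mz, ion_formula = format_formula(ionf),
               theoretical_mz = unname(pick$theo), ppm = unname(pick$ppm),
               interpretation = pick$conv, loss_formula = loss_str,
               loss_label = if (is.na(hit)) NA_character_
                            else losses$label[hit],
               matched = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.data.frame(products) && "rel_intensity_pct" %in% names(products)) {
    out$rel_intensity_pct <- products$rel_intensity_pct
  }
  out
}

#' Count metabolite species and unique molecular formulas
#'
#' Matched precursors are grouped by assigned formula; within a formula,
#' peaks whose retention times differ by more than `rt_split_min` are
#' distinct species (tautomers or positional isomers, as for the
#' thione/thiol pair of 2-thiobenzimidazole). The parent drug and its
#' direct glucuronide are excluded from the metabolite counts and reported
#' separately. Row order of the input does not affect the result.
#'
#' @param matches Output of [match_precursors()].
#' @param rt_split_min RT gap (minutes) above which two peaks of the same
#'   formula are different species.
#' @param parent_formula Neutral formula of the administered drug.
#' @return A `species_report`: list with `species` (data.frame `label`,
#'   `formula`, `rt_min`, `n_peaks`), `species_count`,
#'   `unique_formula_count`, `parent` (rows assigned to the parent or its
#'   glucuronide), `outliers` (unmatched rows and curated overrides).
#' @export
count_species <- function(matches, rt_split_min = 0.5,
                          parent_formula = "C9H10N2S") {
  parent_formula <- format_formula(as_formula(parent_formula))
  # direct glucuronide of the parent: +C6H8O6 (m/z 355.0958 when protonated)
  parent_gluc <- format_formula(apply_delta(parent_formula, add = "C6H8O6"))
  excl <- c(parent_formula, parent_gluc)
  m <- matches[matches$matched %in% TRUE, , drop = FALSE]
  parent_rows <- m[m$formula %in% excl, , drop = FALSE]
  met <- m[!m$formula %in% excl, , drop = FALSE]
  met <- met[order(met$formula, met$rt_min), , drop = FALSE]

  species <- list()
  for (f in unique(met$formula)) {
    grp <- met[met$formula == f, , drop = FALSE]
    cl <- cumsum(c(1, diff(grp$rt_min) > rt_split_min))
    for (k in unique(cl)) {
      sub <- grp[cl == k, , drop = FALSE]
      rt <- mean(sub$rt_min)
      species[[length(species) + 1L]] <- data.frame(
        label = sprintf("%s-RT%.2f", f, rt), formula = f, rt_min = rt,
        n_peaks = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  species <- if (length(species)) do.call(rbind, species) else
    data.frame(label = character(), formula = character(),
               rt_min = numeric(), n_peaks = integer())
  outliers <- matches[!(matches$matched %in% TRUE) |
                        matches$interpretation %in% "curated-override", ,
                      drop = FALSE]
  structure(list(species = species,
                 species_count = nrow(species),
                 unique_formula_count = length(unique(species$formula)),
                 parent = parent_rows, outliers = outliers),
            class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat("<species_report> ", x$species_count, " metabolite species, ",
      x$unique_formula_count, " unique formulas\n", sep = "")
  if (nrow(x$species)) print(x$species, row.names = FALSE)
  invisible(x)
}
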