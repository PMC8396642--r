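#' Read a docked ternary-complex pose
#'
#' Reads ATOM/HETATM records from a PDB file (via `bio3d`) and designates
#' the nucleophile donor atom (the glutathione thiol sulfur) and one or
#' more electrophile acceptor atoms on the ligand (the benzimidazole C2 for
#' the canonical screen; the two vinyl carbons for the vinyl-intermediate
#' screen). Selectors use `"RESIDUE:ATOMNAME"` syntax, e.g. `"GSH:SG"` or
#' `"LIG:C2"`; the donor selector and each acceptor selector must match
#' exactly one atom.
#'
#' @param path PDB file.
#' @param donor Donor selector (default `"GSH:SG"`).
#' @param acceptors Character vector of acceptor selectors (default
#'   `"LIG:C2"`).
#' @return A `pose_complex`: list with `atoms` (data.frame: `serial`,
#'   `name`, `resid`, `chain`, `x`, `y`, `z`), `donor`, `acceptors`
#'   (single-row data.frames), `path`.
#' @export
read_pose <- function(path, donor = "GSH:SG", acceptors = "LIG:C2") {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) {
                    stop(structure(
                      class = c("bemetab_input", "error", "condition"),
                      list(message = paste0("cannot parse PDB '", path,
                                            "': ", conditionMessage(e)),
                           call = sys.call(-1))))
                  })
  a <- pdb$atom
  atoms <- data.frame(serial = a$eleno, name = a$elety, resid = a$resid,
                      chain = ifelse(is.na(a$chain), "", a$chain),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  if (!nrow(atoms) || any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop(structure(
      class = c("bemetab_input", "error", "condition"),
      list(message = paste0("no finite ATOM/HETATM coordinates in '", path,
                            "'"), call = sys.call(-1))))
  }
  sel1 <- function(selector) {
    parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("selector '", selector, "' is not RESIDUE:ATOMNAME",
           call. = FALSE)
    }
    hit <- which(atoms$resid == parts[1] & atoms$name == parts[2])
    if (length(hit) != 1L) {
      stop("selector '", selector, "' matches ", length(hit),
           " atoms (serials: ",
           paste(atoms$serial[hit], collapse = ", "), ")", call. = FALSE)
    }
    atoms[hit, , drop = FALSE]
  }
  structure(list(atoms = atoms, donor = sel1(donor),
                 acceptors = lapply(acceptors, sel1), path = path),
            class = "pose_complex")
}

#' Euclidean distance between two atoms
#'
#' @param a,b Atom records (single-row data.frames with `x`, `y`, `z`) or
#'   numeric length-3 coordinate vectors, in Angstrom.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  xyz <- function(v) {
    if (is.data.frame(v)) as.numeric(v[1, c("x", "y", "z")])
    else as.numeric(v)
  }
  pa <- xyz(a); pb <- xyz(b)
  stopifnot(length(pa) == 3L, length(pb) == 3L,
            all(is.finite(pa)), all(is.finite(pb)))
  sqrt(sum((pa - pb)^2))
}

#' Geometric glutathione-conjugation reactivity screen
#'
#' Nucleophilic attack of the glutathione thiolate on the ligand
#' electrophilic carbon requires the two atoms to sit within bonding reach
#' in the docked ternary complex: the donor-acceptor distance must not
#' exceed the threshold (4 Angstrom by default, inclusive). With several
#' acceptor atoms the minimum distance decides the verdict.
#'
#' @param p A `pose_complex` from [read_pose()].
#' @param threshold Reactivity threshold in Angstrom (default 4.0).
#' @return A `reactivity_assessment`: list with `distances` (one per
#'   acceptor), `dist_s_c2` (their minimum), `threshold`, `verdict`
#'   (`"reactive"`/`"nonreactive"`).
#' @export
assess_conjugation <- function(p, threshold = 4.0) {
  stopifnot(inherits(p, "pose_complex"), threshold > 0)
  d <- vapply(p$acceptors, function(acc) atom_distance(p$donor, acc),
              numeric(1))
  names(d) <- vapply(p$acceptors,
                     function(acc) paste0(acc$resid, ":", acc$name),
                     character(1))
  dmin <- min(d)
  structure(list(distances = d, dist_s_c2 = dmin, threshold = threshold,
                 verdict = if (dmin <= threshold) "reactive"
                           else "nonreactive"),
            class = "reactivity_assessment")
}

#' @export
print.reactivity_assessment <- function(x, ...) {
  cat(sprintf("<reactivity> distS-C %.2f A (threshold %.2f A): %s\n",
              x$dist_s_c2, x$threshold, x$verdict))
  invisible(x)
}
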