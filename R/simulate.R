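#' Chromatogram simulation specification
#'
#' Defines the ground truth of a simulated urine LC-MS/HRMS run: one
#' Gaussian extracted-ion-chromatogram peak per species (RT center, width,
#' area, theoretical precursor m/z) plus global noise settings. Defaults
#' mirror the published run: 0-15 min axis sampled at 0.01 min, 2 ppm mass
#' jitter, baseline noise at 0.1% of the tallest peak.
#'
#' @param species data.frame with columns `label`, `formula`, `rt_min`,
#'   `area`, and optionally `sigma_min` (default 0.05 min) and `mz`
#'   (default the theoretical protonated m/z of `formula`).
#' @param products Optional data.frame of product ions (`label`, `mz`,
#'   `rel_intensity_pct`) keyed to species labels.
#' @param mz_jitter_ppm SD of the multiplicative m/z error, ppm.
#' @param noise_sd_frac Baseline noise SD as a fraction of the tallest
#'   peak height.
#' @param intensity_jitter_frac SD of the relative error on product-ion
#'   intensities.
#' @param dt Sampling interval, min.
#' @param t_max Run length, min.
#' @export
chromatogram_spec <- function(species, products = NULL, mz_jitter_ppm = 2,
                              noise_sd_frac = 0.001,
                              intensity_jitter_frac = 0.05,
                              dt = 0.01, t_max = 15) {
  stopifnot(is.data.frame(species),
            all(c("label", "formula", "rt_min", "area") %in% names(species)))
  if (is.null(species$sigma_min)) {
    species$sigma_min <- rep(0.05, nrow(species))
  }
  if (is.null(species$mz)) {
    species$mz <- vapply(species$formula, protonated_mz, numeric(1),
                         USE.NAMES = FALSE)
  }
  stopifnot(all(species$sigma_min > 0), all(species$area > 0))
  structure(list(species = species, products = products,
                 mz_jitter_ppm = mz_jitter_ppm,
                 noise_sd_frac = noise_sd_frac,
                 intensity_jitter_frac = intensity_jitter_frac,
                 dt = dt, t_max = t_max),
            class = "chromatogram_spec")
}

#' Ground truth emulating the published metabolite run
#'
#' The nine metabolite species plus the parent drug at their published
#' retention times, with relative areas honouring the published
#' chromatographic ratios: 60:1 for the 2-thiobenzimidazole tautomer pair
#' (M1a:M1b), 40:1 for M2a:M2b, 1:10 for the two M3 peaks; the
#' N-acetylcysteine conjugate M5 and the hydroxy-sulfate M4 are the most
#' abundant metabolites and the glucuronide M6 is minor. Product-ion
#' intensities are taken from the packaged peak-table transcription
#' (unreported values default to 10%). The M5 species carries the
#' theoretical m/z of its formula; the anomalous published precursor value
#' lives only in the transcribed table.
#'
#' @return A [chromatogram_spec()].
#' @export
table2_ground_truth <- function() {
  fx <- load_paper_fixtures()
  species <- data.frame(
    label   = c("bemethyl", "M1a", "M1b", "M2a", "M2b", "M3-1", "M3-2",
                "M4", "M5", "M6"),
    formula = c("C9H10N2S", "C7H6N2S", "C7H6N2S", "C9H10N2OS", "C9H10N2OS",
                "C9H10N2O3S", "C9H10N2O3S", "C9H10N2O4S2", "C12H13N3O3S",
                "C15H18N2O7S"),
    rt_min  = c(10.70, 9.40, 11.01, 9.13, 11.42, 9.26, 10.51, 9.14, 9.37,
                8.21),
    area    = c(3, 60, 1, 40, 1, 2, 20, 80, 100, 5),
    stringsAsFactors = FALSE)
  prod <- fx$peaks[fx$peaks$role == "product", ]
  relabel <- c(M3a = "M3-1", M3b = "M3-2")
  lab <- prod$parent_compound
  lab[lab %in% names(relabel)] <- relabel[lab[lab %in% names(relabel)]]
  products <- data.frame(label = lab, mz = prod$mz,
                         rel_intensity_pct =
                           ifelse(is.na(prod$rel_intensity_pct), 10,
                                  prod$rel_intensity_pct),
                         stringsAsFactors = FALSE)
  chromatogram_spec(species, products = products)
}

#' Simulate an LC-MS/HRMS run
#'
#' Generates one extracted-ion chromatogram per species (Gaussian peak plus
#' additive baseline noise), jitters the precursor and product m/z values
#' by the ppm-scale mass error, draws product-ion intensities around their
#' ground-truth percentages, and derives a [peak_table()] by apex detection
#' and trapezoidal integration. Fully reproducible per seed.
#'
#' @param spec A [chromatogram_spec()].
#' @param seed Integer RNG seed.
#' @return A `simulated_run`: list with `time`, `traces` (named list of
#'   intensity vectors), `peak_table` (provenance `"simulated"`), `areas`
#'   (integrated areas by species), and `truth` (the spec and seed).
#' @examples
#' run <- simulate_run(table2_ground_truth(), seed = 1)
#' run$areas[["M1a"]] / run$areas[["M1b"]]  # close to 60
#' @export
simulate_run <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "chromatogram_spec"))
  set.seed(seed)
  tm <- seq(0, spec$t_max, by = spec$dt)
  sp <- spec$species
  n <- nrow(sp)
  heights <- if (n) sp$area / (sp$sigma_min * sqrt(2 * pi)) else 1
  noise_sd <- spec$noise_sd_frac * max(heights, 1e-12)

  traces <- list()
  rows <- list()
  areas <- numeric(0)
  if (n) {
    for (i in seq_len(n)) {
      y <- sp$area[i] * stats::dnorm(tm, sp$rt_min[i], sp$sigma_min[i]) +
        stats::rnorm(length(tm), 0, noise_sd)
      traces[[sp$label[i]]] <- y
      apex <- tm[which.max(y)]
      win <- c(max(min(tm), apex - 4 * sp$sigma_min[i]),
               min(max(tm), apex + 4 * sp$sigma_min[i]))
      areas[sp$label[i]] <-
        integrate_peak(data.frame(time = tm, intensity = y), win)
      mz_obs <- sp$mz[i] *
        (1 + stats::rnorm(1, 0, spec$mz_jitter_ppm) * 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        role = "precursor", compound = sp$label[i], rt_min = apex,
        mz = mz_obs, rel_intensity_pct = 100,
        parent_compound = NA_character_, stringsAsFactors = FALSE)
      if (!is.null(spec$products)) {
        pr <- spec$products[spec$products$label == sp$label[i], ,
                            drop = FALSE]
        if (nrow(pr)) {
          pmz <- pr$mz * (1 + stats::rnorm(nrow(pr), 0,
                                           spec$mz_jitter_ppm) * 1e-6)
          pint <- pmin(100, pmax(0, pr$rel_intensity_pct *
            (1 + stats::rnorm(nrow(pr), 0, spec$intensity_jitter_frac))))
          rows[[length(rows) + 1L]] <- data.frame(
            role = "product", compound = sp$label[i], rt_min = apex,
            mz = pmz, rel_intensity_pct = pint,
            parent_compound = sp$label[i], stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    traces[["baseline"]] <- stats::rnorm(length(tm), 0, noise_sd)
  }
  pt <- if (length(rows)) {
    peak_table(do.call(rbind, rows), provenance = "simulated")
  } else {
    peak_table(data.frame(role = character(), compound = character(),
                          rt_min = numeric(), mz = numeric())[0, ],
               provenance = "simulated")
  }
  structure(list(time = tm, traces = traces, peak_table = pt,
                 areas = areas, truth = list(spec = spec, seed = seed)),
            class = "simulated_run")
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the trace over the window, above a constant
#' baseline fitted as the median intensity of the flanking regions on
#' either side of the window (each of width `margin`, clipped to the
#' trace). Fitting the baseline outside the integration window keeps the
#' window tight around the peak while averaging the baseline over many
#' samples, which is what bounds the error on low-abundance peaks. When no
#' flanking samples exist (window spans the trace) the window's own edge
#' samples are used.
#'
#' @param trace data.frame with columns `time` and `intensity`.
#' @param window Length-2 numeric `c(lo, hi)` in the trace's time units;
#'   must lie within the trace.
#' @param margin Width of each flanking baseline region (default: the
#'   window width).
#' @return Area in intensity x time units.
#' @export
integrate_peak <- function(trace, window, margin = diff(window)) {
  stopifnot(is.data.frame(trace),
            all(c("time", "intensity") %in% names(trace)),
            length(window) == 2L, window[1] < window[2])
  if (window[1] < min(trace$time) - 1e-9 ||
      window[2] > max(trace$time) + 1e-9) {
    stop("integration window [", window[1], ", ", window[2],
         "] outside trace range", call. = FALSE)
  }
  idx <- which(trace$time >= window[1] & trace$time <= window[2])
  if (length(idx) < 4L) stop("integration window too narrow", call. = FALSE)
  flank <- which((trace$time >= window[1] - margin &
                    trace$time < window[1]) |
                   (trace$time > window[2] &
                      trace$time <= window[2] + margin))
  baseline <- if (length(flank) >= 4L) {
    stats::median(trace$intensity[flank])
  } else {
    y <- trace$intensity[idx]
    k <- min(3L, length(idx) %/% 2L)
    stats::median(c(utils::head(y, k), utils::tail(y, k)))
  }
  pracma::trapz(trace$time[idx], trace$intensity[idx] - baseline)
}

#' Write a synthetic pose fixture
#'
#' Writes a minimal synthetic PDB complex with the glutathione SG atom and
#' the ligand C2 atom at exactly the requested separation, plus a few
#' bystander atoms, randomly translated and oriented along a random
#' coordinate axis per seed (axis-aligned so the separation is represented
#' exactly within the PDB's three-decimal coordinate fields). Byte-identical
#' output for a fixed seed.
#'
#' @param path Output PDB path.
#' @param distance Requested SG-C2 separation, Angstrom (> 0).
#' @param seed Integer RNG seed.
#' @return `path`, invisibly.
#' @export
make_pose_fixture <- function(path, distance, seed = 1L) {
  stopifnot(distance > 0)
  set.seed(seed)
  origin <- round(stats::runif(3, -5, 5), 3)
  axis <- sample(3L, 1L)
  sgn <- sample(c(-1, 1), 1L)
  sg <- origin
  c2 <- origin
  c2[axis] <- c2[axis] + sgn * round(distance, 3)
  decoy1 <- round(origin + stats::runif(3, 2, 6), 3)
  decoy2 <- round(origin - stats::runif(3, 2, 6), 3)

  rec <- function(record, serial, name, resname, chain, resseq, p, elem) {
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, resname, chain, resseq,
            p[1], p[2], p[3], 1.00, 0.00, elem)
  }
  lines <- c(
    "REMARK   synthetic pose fixture (not a docking output)",
    rec("ATOM",   1L, "CA", "ALA", "A", 1L, decoy1, "C"),
    rec("HETATM", 2L, "SG", "GSH", "B", 2L, sg, "S"),
    rec("HETATM", 3L, "N1", "LIG", "B", 3L, decoy2, "N"),
    rec("HETATM", 4L, "C2", "LIG", "B", 3L, c2, "C"),
    "END")
  writeLines(lines, path)
  invisible(path)
}
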