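#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "bemetab")
  if (!nzchar(p)) stop("fixture '", name, "' not found", call. = FALSE)
  p
}

# md5 of the shipped transcriptions; load_paper_fixtures() refuses to serve
# a silently edited copy
.FIXTURE_MD5 <- c(
  "peaks_table2.csv"       = "656a3aec9bac359d0465a2ab1c2bdfdc",
  "acquisition_table3.csv" = "fbfafe2b81a266d6a49c0af9929bdd57",
  "pathway_scores.csv"     = "2f0b0e431090d962f7c0cba645287974",
  "parent_formulas.csv"    = "989e1703da9ed625de8cc674df95710b"
)

#' Load the packaged in-paper reference tables
#'
#' Returns the published chromatographic/tandem-MS peak table of bemethyl
#' and its nine urinary metabolites, the per-compound acquisition windows
#' and collision energies, the scored oxidation-pathway table, and the
#' parent-drug formula table, transcribed into plain CSV fixtures and
#' checksummed.
#'
#' @param check Verify the md5 checksums of the fixture files (default
#'   TRUE); a mismatch raises an error of class `bemetab_corrupt_fixture`.
#' @param dir Directory holding the fixture CSVs; defaults to the
#'   package's own copies.
#' @return List with elements `peaks` (a [peak_table()]), `acquisition`,
#'   `scores` (edge table), `parents`, and `graph` (the scored
#'   `metabolite_graph` built from `scores`).
#' @export
load_paper_fixtures <- function(check = TRUE, dir = NULL) {
  fixture_path <- if (is.null(dir)) fixture_path else
    function(nm) file.path(dir, nm)
  if (check) {
    for (nm in names(.FIXTURE_MD5)) {
      got <- unname(tools::md5sum(fixture_path(nm)))
      if (!identical(got, unname(.FIXTURE_MD5[nm]))) {
        stop(structure(
          class = c("bemetab_corrupt_fixture", "error", "condition"),
          list(message = paste0("fixture ", nm, " is corrupted (md5 ", got,
                                ", expected ", .FIXTURE_MD5[nm], ")"),
               call = sys.call(-1))))
      }
    }
  }
  list(
    peaks = read_peak_table(fixture_path("peaks_table2.csv"),
                            provenance = "paper-transcribed"),
    acquisition = utils::read.csv(fixture_path("acquisition_table3.csv"),
                                  stringsAsFactors = FALSE),
    scores = utils::read.csv(fixture_path("pathway_scores.csv"),
                             stringsAsFactors = FALSE),
    parents = utils::read.csv(fixture_path("parent_formulas.csv"),
                              stringsAsFactors = FALSE),
    graph = bemethyl_score_graph(fixture_path("pathway_scores.csv"))
  )
}
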