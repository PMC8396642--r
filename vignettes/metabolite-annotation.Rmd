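---
title: "Annotating bemethyl urinary metabolites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating bemethyl urinary metabolites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bemetab)
```

## The problem

Bemethyl, 2-(ethylthio)benzimidazole (C9H10N2S), is an actoprotector whose
urinary elimination products matter for doping control and for
understanding its pharmacology, yet the parent drug itself is excreted
almost entirely transformed. Identifying its metabolites from a urine
LC-MS/HRMS run is an exercise in joint reasoning over several weak signals:
accurate precursor masses, product-ion (MS/MS) sub-formulas and neutral
losses, isotope envelopes, chromatographic retention, and the biochemical
plausibility of each candidate as a phase I/II transformation product of
the parent. `bemetab` implements that reasoning as a pipeline of small,
separately testable components.

## Formula arithmetic and ion masses

Everything rests on exact elemental bookkeeping over CHNOS. A formula is a
non-negative count vector; its monoisotopic mass is the lightest-isotope
atom sum from an isotope table pinned inside the package (masses and
abundances fixed at construction, so results cannot drift with external
reference data). Positive-mode electrospray of these analytes produces
singly protonated even-electron cations, so the observable m/z of a neutral
M is `mass(M) + 1.00727646` Th. Equivalently, the atom sum of M+H minus one
electron mass; the two routes agree to within 10 nTh and both are exposed.

Published product-ion tables are not always consistent about the electron
(or the proton): the same table can print one ion at the plain atom sum,
another electron-subtracted, a third only interpretable as composition-plus-
proton. The annotator therefore scores each candidate composition under the
physically correct cation convention first and the plain atom sum as a
fallback, and records per match which interpretation applied. This is a
deliberate tolerance for the realities of printed tables, not a physical
claim.

## Formula decomposition

`decompose_mz()` enumerates every CHNOS formula within configurable count
bounds whose protonated m/z lies within a ppm tolerance of the query. The
default tolerance is 5 ppm — an Orbitrap-class figure consistent with the
sub-5-ppm agreement between the published precursor masses and theory — and
the default bounds (C≤20, H≤30, N≤5, O≤8, S≤3) cover the metabolite space
of a two-sulfur parent up to a glucuronide-sized conjugate. Candidates are
ranked by absolute ppm error with deterministic tie-breaks (fewer
heteroatoms, then Hill string); ranking ties essentially never occur at
these tolerances, so the tie-break is there for reproducibility, not
science. The search loop prunes on partial mass but the test suite holds it
to exact set equality against a full-grid brute-force oracle.

One precursor is special: the published M5 precursor (280.0689) sits about
22 ppm below the theoretical protonated C12H13N3O3S (≈280.0750). No
tolerance a practitioner would defend covers 22 ppm, so the package treats
M5 as a curated assignment: the peak is annotated with the published
formula under an explicit `curated-override` flag, and the computed
discrepancy is preserved in every report rather than silently corrected on
either side.

## Isotope patterns and sulfur counting

`formula_pattern()` convolves per-element isotope distributions exactly and
aggregates isotopologues into unit-mass bins. For CHNOS every heavy isotope
shifts nominal mass by its neutron count, so binning at ±0.3 Da around
integer offsets is exact; fine structure (e.g. ³⁴S against ¹³C₂ inside M+2)
is deliberately aggregated, because the identification argument operates at
unit resolution. The M+2 bin of a sulfur-bearing ion is dominated by ³⁴S
(4.25%), which makes the observed M+2/M ratio an effective sulfur counter:
`estimate_sulfur_count()` returns the sulfur count (searched 0–4, ties to
the smaller count) whose predicted ratio is nearest the observation. The
search cap reflects the chemistry — metabolites of a two-sulfur parent do
not exceed four sulfurs. Only M+2 enters the estimate; M+1 is mostly ¹³C
and, in the published M4 envelope, disagrees with theory (printed 10%
against a theoretical ≈12%) in a way the M+2-based argument does not.

## The biotransformation network

Transformation rules are formula deltas guarded by functional-group tags
(thioether, sulfoxide, aromatic-OH, ...). This is a considered choice of
abstraction level: the mass spectra do not fix the position of a ring
hydroxyl, but its *presence* is what licenses sulfation and
glucuronidation, and the sulfoxide is what licenses glutathione attack at
the benzimidazole C2. The packaged rule set covers S-oxidation to sulfoxide
and sulfone, aromatic and alpha-carbon hydroxylation, oxidative
S-de-ethylation to 2-thiobenzimidazole, sulfation, glucuronidation, and the
mercapturic-acid chain (glutathione displacement of the ethylsulfinyl
group, then GGT, CGDP and NAT steps to the N-acetylcysteine conjugate).
`expand_metabolites()` applies all feasible rules breadth-first with
deduplication by (formula, tag set); depth 5 is the default pipeline
setting because the mercapturic chain needs five transformations from the
parent.

Pathway plausibility is scored by treating per-step metabolite scores as
probabilities: a pathway's score is the product of its edge scores and a
metabolite's total is the sum over all simple root-to-target pathways. No
normalization is applied — the aggregation is implemented exactly as
defined, and whether summed products of unnormalized scores behave like
probabilities is a caveat the package inherits rather than endorses. On the
packaged scored graph this yields 9.69 for the triple-ring-oxidation
candidate M3a (one pathway) and 107.99 for the hydroxylated sulfone M3b
(three pathways), the comparison that favours reading the M3 signal as
predominantly sulfone.

Two intermediates in the scored graph share the hydroxy-sulfoxide formula
but are kept as distinct nodes (`HOSO-a`, reached sulfoxide-first, and
`HOSO-b`, hydroxyl-first): their published formation scores differ by
provenance, and collapsing them into one node would make a
single-score-per-edge DAG unable to reproduce all three published per-path
score triplets at once. Keeping provenance-distinct intermediates preserves
every printed score exactly.

## Peak annotation and species accounting

Precursors are matched to the candidate formula of smallest absolute ppm
error within tolerance; unmatched peaks keep their best out-of-tolerance
candidate and its ppm so that nothing silently disappears. Product ions are
assigned elemental sub-formulas of their precursor ion, and the
complementary loss is labelled from a small neutral-loss table (ethene, CO,
water, SO, SO3, glucuronyl, and the mercapturic-pathway residues) when its
formula is listed there.

Species counting groups matched precursors by formula and splits a group
into separate species where retention times differ by more than
`rt_split_min` (default 0.5 min: the observed tautomer/isomer pairs are
≥1.25 min apart, while simulated RT scatter is far below 0.5 min). The
parent drug and its direct glucuronide are excluded from the metabolite
counts and reported separately. Because the spectra cannot assign which M3
peak is the sulfone, species are labelled by formula and retention time
(`C9H10N2O3S-RT9.26`), never structurally. On the packaged transcription
this yields 9 metabolite species across 6 molecular formulas.

## The geometric conjugation screen

The glutathione-conjugation criterion is purely geometric: in a docked
GST–GSH–ligand ternary complex, nucleophilic attack on the benzimidazole
C2 requires the glutathione sulfur within 4 Å of it. The package reads
ATOM/HETATM records, selects donor and acceptor atoms by `RESIDUE:ATOMNAME`
selectors, and classifies the minimum donor–acceptor distance against the
threshold, inclusive at exactly 4.0 Å (the criterion is "must not exceed").
Multiple acceptors are supported for the vinyl-intermediate variant of the
screen, where the distances to both vinyl carbons are reported and the
minimum decides. Docking and energy minimization themselves are out of
scope: poses enter as coordinate files, and the published distances (5.72 Å
for the parent — nonreactive; 3.65 and 3.83 Å for sulfoxide and sulfone —
reactive; 4.59/4.03 Å for the vinyl route — nonreactive) are classification
inputs, not recomputable outputs.

## What the simulator emulates — and what it does not

`simulate_run()` generates one Gaussian extracted-ion chromatogram per
species on a 0–15 min axis at 0.01 min sampling (the published run length),
with additive baseline noise, ppm-scale m/z jitter, and product-ion
intensities drawn around their table values. The default conditions are
fixed by the study being emulated: tautomer/isomer area ratios 60:1 (M1),
40:1 (M2) and 1:10 (M3); the N-acetylcysteine conjugate M5 and the
hydroxy-sulfate M4 as the most abundant metabolites and the glucuronide M6
minor; m/z jitter 2 ppm (consistent with the sub-5-ppm accuracy of the
published table); baseline noise 0.1% of the tallest peak; peak sigma
0.05 min, a typical width on a sub-2-µm column. The simulated M5 carries
the theoretical m/z of its formula — the anomalous published value lives
only in the transcribed table, so the curated-override path is exercised by
the transcription and the regular path by the simulation.

Peak areas are recovered by trapezoidal integration over apex ±4 sigma
above a constant baseline fitted as the median of flanking regions on
either side of the window. Fitting the baseline outside the window is what
bounds the error on low-abundance peaks: the area error scales as window
width divided by the square root of the number of baseline samples, so a
tight window with wide flanks recovers even the 60:1 pair within a few
percent per run.

The simulator is honest about its limits: peaks are symmetric Gaussians
(no tailing or fronting), the baseline is white noise without drift or
matrix ridges, co-eluting isobaric interference and ion suppression are
absent, and product-ion intensities are independent draws rather than
spectra from a fragmentation model. Passing the end-to-end test on
simulated data therefore demonstrates that the annotation logic is correct
under the stated statistical structure, not that the pipeline is robust to
every artefact of real urine runs.

## Numerical and degenerate-input choices

- Isotope masses/abundances, the proton (1.00727646 Da) and electron
  (0.00054858 Da) masses are package constants; m/z is kept at full
  precision and rounded to 4 decimals only for presentation.
- Infeasible rule applications (negative element counts) raise a typed
  condition and are skipped during expansion; an empty rule set gives the
  one-node graph; an unreachable scoring target totals 0 over an empty
  path set, and the root itself scores 1.0 (empty product).
- Empty peak tables annotate to zero counts without error; a malformed or
  unreadable CSV raises a typed input error (exit code 2 at the CLI).
- Pose fixtures are axis-aligned after random translation so the requested
  donor-acceptor separation is representable exactly in the PDB's
  three-decimal coordinate fields; fixture generation is byte-identical
  per seed.
- Test problem sizes: the decomposition oracle runs 50 random masses over
  the full default grid; the enumeration oracle covers formulas of at most
  10 atoms; ratio-recovery statistics use 20 seeds. The full suite runs in
  well under a minute.

## Known limitations

The package reasons at formula level throughout: it cannot distinguish
hydroxylation from S-oxidation (both +O) — the published work names
hydrogen/deuterium exchange as the experiment that would — and it does not
model tautomer thermodynamics, so the two M1 peaks are two species by
retention time, not assigned thione/thiol identities. The pathway scores
are packaged published values, not recomputed: the underlying
site-of-metabolism model is a machine-learned external tool and out of
scope. Raw-spectrum processing (centroiding, deisotoping) and mzML
ingestion are likewise out of scope; the pipeline starts from a peak table.
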