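# bemetab

Identification of the urinary metabolites of **bemethyl**
(2-(ethylthio)benzimidazole, C9H10N2S), an actoprotector on the WADA
monitoring program, from LC–MS/HRMS peak tables. The package is aimed at
analytical and forensic toxicologists and at developers of metabolite
identification workflows who want every inference step — exact-mass
assignment, isotope reasoning, biotransformation plausibility, geometric
conjugation screening — as transparent, tested code rather than
point-and-click software.

## What it computes

**Ion masses.** Metabolites appear as protonated even-electron cations, so
a neutral M is observed at

> m/z([M+H]⁺) = mass(M) + m_p,  with m_p = 1.00727646 Da,

with monoisotopic masses summed from an isotope table pinned in the
package. Accuracy is tracked as ppm error, (obs − theo)/theo × 10⁶.

**Formula decomposition.** All CHNOS formulas within count bounds whose
[M+H]⁺ falls within a ppm tolerance of a query mass, ranked by |ppm|, with
an RDBE filter (RDBE = C − H/2 + N/2 + 1). Verified against a brute-force
grid oracle.

**Isotope patterns.** Exact multinomial convolution of elemental isotope
distributions into unit-mass bins. Because ³⁴S (4.25%) dominates M+2, the
observed M+2/M ratio counts sulfur atoms: the hydroxy-sulfate metabolite
M4 shows M+2 ≈ 10% of base, which the estimator reads as two sulfurs.

**Biotransformation network.** Phase I/II transformation rules (formula
deltas guarded by functional-group tags) expand the parent into a
metabolite DAG; pathway plausibility treats per-step scores as
probabilities — product along a pathway, sum over pathways:

> S(target) = Σ_paths Π_edges s_e

which gives 9.69 for the triple-ring-oxidation candidate M3a and 107.99
for the hydroxylated sulfone M3b.

**Peak annotation.** Precursor matching within tolerance, product-ion
sub-formula assignment with neutral-loss labels (e.g. loss of C6H8O6,
176.0321 Da, marks a glucuronide), retention-time splitting of
equal-formula species (tautomers/isomers), and species/formula counting.

**Conjugation screen.** In a docked GST–glutathione–ligand complex,
glutathione attack at the benzimidazole C2 is geometrically possible when
dist(S, C2) ≤ 4 Å (inclusive); poses are read from PDB files with
`RESIDUE:ATOMNAME` selectors.

A chromatogram simulator (`simulate_run()`) generates full synthetic runs
with the study's area ratios, mass jitter and noise, so the entire
pipeline is testable without any instrument data.

## Worked example

```r
library(bemetab)

# exact mass of the parent ion
protonated_mz("C9H10N2S")
#> [1] 179.0637

# annotate the packaged peak-table transcription
rep <- run_annotate(load_paper_fixtures()$peaks)
rep
#> <annotation_report> 10 precursors, 9 metabolite species, 6 unique formulas (1 curated override)
rep$species$species
#>               label     formula rt_min n_peaks
#>  C12H13N3O3S-RT9.37 C12H13N3O3S   9.37       1
#>  C15H18N2O7S-RT8.21 C15H18N2O7S   8.21       1
#>      C7H6N2S-RT9.40     C7H6N2S   9.40       1
#>     C7H6N2S-RT11.01     C7H6N2S  11.01       1
#>   C9H10N2O3S-RT9.26  C9H10N2O3S   9.26       1
#>  C9H10N2O3S-RT10.51  C9H10N2O3S  10.51       1
#>  C9H10N2O4S2-RT9.14 C9H10N2O4S2   9.14       1
#>    C9H10N2OS-RT9.13   C9H10N2OS   9.13       1
#>   C9H10N2OS-RT11.42   C9H10N2OS  11.42       1

# score the competing structures for the triply oxygenated metabolite M3
run_score("M3b")
#> <score_report> M3b: total 107.99 over 3 pathway(s)
#>     26.88  bemethyl -> M2a -> HOSO-a -> M3b
#>     43.82  bemethyl -> M2a -> T2 -> M3b
#>     37.29  bemethyl -> M2b -> HOSO-b -> M3b
```

Nine species across six formulas: the 2-thiobenzimidazole tautomer pair
(C7H6N2S), two C9H10N2OS structures (sulfoxide and ring hydroxide), two
retention-time isomers of C9H10N2O3S, the two-sulfur hydroxy-sulfate M4,
the N-acetylcysteine conjugate M5 (retained by a curated override — its
published precursor mass is ~22 ppm from theory, a discrepancy the report
preserves), and the hydroxylated glucuronide M6. The parent drug is
reported separately, not counted as a metabolite. The M3b total of 107.99
versus 9.69 for M3a is the basis for reading the M3 signal as
predominantly the hydroxylated sulfone.

A thin command-line front end is included at `inst/cli/bemetab.R`
(subcommands `annotate`, `enumerate`, `score`, `simulate`, `pose`).

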