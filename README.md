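# snokturn

Tools for analysing how N6-methylation of a conserved adenine (the k-turn
**A1n** position) controls the first step of box C/D snoRNP assembly.

Box C/D snoRNAs fold into kink-turns (k-turns) whose sheared G·A pairs are
recognized by the 15.5K/Snu13 protein to nucleate snoRNP assembly. The A1n
adenine of the box D (or D') `CUGA` element frequently sits in a
`GAC`/`DRACH` context — the substrate motif of the METTL3/METTL14 m6A
writer — and its N6-methyl group points straight into the sheared-pair
interface. This package provides the computational side of that story:

* **Motif annotation** — locate box C/D and C'/D' elements, assign
  standard k-turn position nomenclature (`-1b … 2b`, `3n … -2n`), and flag
  GAC/DRACH methylation targets at A1n (`find_boxes`, `annotate_kturn`,
  `scan_gac_target`, `scan_sequence_set`).
* **Conservation** — column/pair frequencies and `-1n` cytosine
  conservation across ortholog alignments, with a rank test between
  methylated and unmethylated families (`minus1n_conservation`,
  `group_compare`).
* **Genomic cross-referencing** — map A1n transcript positions to genomic
  coordinates and intersect them with m6A site tables
  (`map_a1n_to_genome`, `crossref_modsites`, `summarize_crossref`).
  Curated human and mouse A1n m6A site tables ship in `inst/extdata/`.
* **Binding models** — the protein-induced-folding FRET isotherm
  (quadratic tight-binding solution) and the one-set-of-sites ITC model
  with derived thermodynamics (`efret_model`, `fit_fret`, `fit_itc`).
* **Structure geometry** — hydrogen-bond detection, Leontis-Westhof
  edge/orientation classification, sheared-G·A detection, N6-methyl
  placement and clash checking, and Kabsch superposition
  (`classify_pair`, `detect_sheared_GA`, `add_n6_methyl`, `clash_check`,
  `superpose`).
* **Synthetic data** — generators with recorded ground truth for every
  stage, and an end-to-end pipeline (`gen_snorna_set`,
  `gen_duplex_coords`, `run_kturn_pipeline`).

See `vignettes/methods.Rmd` for the conventions and model equations.

## Worked example

```r
library(snokturn)

# Generate snoRNA-like sequences with planted boxes, then scan them back
g <- gen_snorna_set(n = 4, seed = 42)
seqs <- lapply(names(g$sequences), function(i) snorna(i, g$sequences[[i]]))
sc <- scan_sequence_set(seqs)
sc[, c("id", "role", "boxC_start", "boxD_start", "a1n_pos",
       "context5", "is_gac", "is_drach")]
#>          id role boxC_start boxD_start a1n_pos context5 is_gac is_drach
#> 1 synth_001 boxD          6         43      46    UGACA   TRUE     TRUE
#> 2 synth_002 boxD          6         43      46    UGACU   TRUE     TRUE
#> 3 synth_003 boxD          6         43      46    UGACC   TRUE     TRUE
#> 4 synth_004 boxD          6         43      46    UGACC   TRUE     TRUE

# Summarize the bundled human A1n m6A site table
human <- read_modsites(system.file("extdata", "a1n_m6a_sites_human.tsv",
                                   package = "snokturn"))
summarize_crossref(human)
#> collapsed paralog names: SNORD62A -> SNORD62, SNORD62B -> SNORD62
#> <crossref_summary> 19 site records at 19 unique positions, 14 unique RNAs
#>   (8 box D + 6 box D'); max support 11 (SNORD13)

# Fit a noisy FRET titration (truth: E0 = 0.1, dE = 0.5, K_A = 2e7)
gf <- gen_fret_curve(noise_sd = 0.01, seed = 7)
fit_fret(gf$data)
#> <fret_fit> E0 = 0.0965, dE = 0.5007, K_A = 1.86e+07 M^-1 (identifiable)

# Classify a planted sheared G·A pair and check the N6-methyl clash
gd <- gen_duplex_coords(planted = "sheared", seed = 1)
n <- nrow(gd$truth)
classify_pair(gd$residues[[3]], gd$residues[[n + 3]])
#> <base_pair> A:3G -- B:10A: trans Sugar/Hoogsteen G·A (3 H-bonds)
clash_check(add_n6_methyl(gd$residues[[n + 3]], "syn"), gd$residues[[3]])
#> $min_distance
#> [1] 2.03163
#> $clashing
#> [1] TRUE
#> $closest
#>       methyl partner_atom
#>        "CM6"        "O2'"
```

The methyl carbon lands 2.03 Å from the partner guanine's O2' — far
inside van der Waals contact — which is why N6-methylation of A1n blocks
sheared-pair formation while a Watson-Crick A-U pair accommodates the
methyl in the major groove (`clash_check` returns `clashing = FALSE`
there).

## Tests

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "snokturn",
                               load_package = "installed")'
```

One acceptance test is expected to fail in an offline environment: it
validates deposited crystal-structure coordinates that must be placed
manually at `inst/extdata/structures/5LR3.pdb` and
`inst/extdata/structures/5LR4.pdb` (they cannot be downloaded here). All
other tests pass.

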