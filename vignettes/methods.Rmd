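---
title: "Methods: k-turn annotation, binding models, and pair-geometry classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-turn annotation, binding models, and pair-geometry classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snokturn)
```

This vignette records the conventions, model equations, and idealizations
behind each module, in enough detail to reproduce or audit the results.

## 1. Box motifs and k-turn position nomenclature

Box C is matched as the IUPAC pattern `RUGAUGA`, box D as `CUGA`
(`find_boxes`, optional mismatch budget). A terminal k-turn is a box C
upstream of a box D (`role = "boxCD"`); an internal k-turn is a box D'
upstream of a box C' (`role = "boxC'D'"`). When both exist,
`scan_sequence_set` reports the terminal candidate as role `boxD` and the
internal one as `boxD'`.

`annotate_kturn` assigns standard k-turn position labels:

* **Bulged strand (box C).** The first box C nucleotide is `-1b`;
  nucleotides 2-5 are the three-nucleotide loop `L1`-`L3` plus one extra
  loop position; nucleotides 6 and 7 are `1b` and `2b`.
* **Non-bulged strand (box D).** Reading the `CUGA` element backwards from
  its 3' end: the terminal `A` is `1n` (the A1n adenine), `G` is `2n`, `U`
  is `3n`. The nucleotide immediately 3' of box D is `-1n`, the next one
  `-2n`.
* **C helix.** If the segment between the boxes is internal, at most 8 nt
  long, and forms fewer than 2 Watson-Crick/wobble pairs against the other
  strand, the element is called a *k-loop*; a terminal element whose flanks
  form at least 2 pairs is a *duplex*.

`scan_gac_target` extracts the 5-mer context `(3n, 2n, 1n, -1n, -2n)`
centered on A1n. `is_drach` is true when that 5-mer matches `DRACH`
(D = A/G/U, R = A/G, H = A/C/U). `is_gac` is true when the central triplet
is exactly `GAC` *and* the 5-mer is a DRACH instance (equivalently: the
5-mer matches `DGACH`); the bare triplet is always returned in `triplet`
so a GAC core outside a DRACH context remains visible. With this
definition every GAC-type target is, by construction, a DRACH target —
the invariant that downstream conservation and cross-referencing code
relies on.

## 2. Conservation statistics

`multiple_alignment` normalizes rows (uppercase, `T` to `U`, `.` to `-`)
and rejects other characters. `column_frequencies` counts base fractions
per column, with gaps either included in or excluded from the denominator.
`minus1n_conservation` projects the `-1n` position of an annotated
reference row through the alignment (counting non-gap reference positions)
and reports the percentage of rows carrying `C` in that column.
`group_compare` applies an exact Wilcoxon rank-sum test to the `-1n` C
percentages of two sets of family reports.

## 3. Genomic cross-referencing

`gene_model` holds one gene span; `map_a1n_to_genome` converts a 1-based
transcript index to a genomic position (`start + i - 1` on `+`,
`end - i + 1` on `-`), and `genome_to_transcript` inverts it.
`crossref_modsites` joins annotated A1n loci against a site table on
chromosome, strand, and position within a slack; unmatched loci are kept
with `methylated = FALSE`. `summarize_crossref` collapses paralogs that
differ only by a trailing letter suffix (e.g. two loci of the same
family collapse to one name stem), splits genes into box D versus box D'
classes by their k-turn position label, and reports the maximal-support
record. Conflicting role labels for one gene are an error, not a vote.

## 4. Binding models

**FRET isotherm.** For protein total $P_T$, RNA total $R_T$, and
association constant $K_A$, the complex concentration is the stable root
of $K_A C^2 - (1 + K_A(P_T + R_T))C + K_A P_T R_T = 0$, computed in the
cancellation-free form $C = 2ab/(-b + \sqrt{b^2 - 4ac})$-style rearrangement
to keep ten decimal digits at nanomolar concentrations. The observable is
$E(P_T) = E_0 + \Delta E \cdot C / R_T$, so $E(0) = E_0$ exactly and
$E \to E_0 + \Delta E$ at saturation. `fit_fret` estimates
$(E_0, \Delta E, K_A)$ by Levenberg-Marquardt least squares and profiles
$K_A$ to flag non-identifiable (stoichiometric-regime) fits and degenerate
(flat) curves.

**ITC.** `itc_one_site_heats` implements the one-set-of-sites model with
per-injection cell dilution: after injection $j$ the cell concentrations
are down-weighted by the cumulative displaced volume, bound ligand is the
same quadratic root as above with stoichiometry $n$, and the heat is
$q_j = \Delta H V_0 \Delta[\mathrm{bound}]_j$ (corrected for the displaced
aliquot). `fit_itc` recovers $(\Delta H, K, n)$ and derives
$\Delta G = -RT\ln K$, $\Delta S = (\Delta H - \Delta G)/T$, and
$K_d = 1/K$ with $R = 1.9872$ cal mol$^{-1}$ K$^{-1}$ and $T = 298$ K.

## 5. Pair geometry and Leontis-Westhof classification

`find_hbonds` pairs donor hydrogens' heavy-atom antecedents with acceptors
at $\le 3.5$ Å; the donor-antecedent-acceptor angle is measured against
the *full base-ring centroid* of the donor residue and must exceed 90°.
Base-base bonds are flagged separately from bonds involving ribose
oxygens.

`classify_pair` assigns each interacting base an edge (Watson-Crick,
Hoogsteen, or Sugar) by voting over its hydrogen bonds: each base-base
bond contributes a full vote to the edge that owns its atom, contacts
through the O2' hydroxyl contribute half votes to the Sugar edge, and an
edge within 0.6 votes of the leader yields the tie-breaking rule rather
than a hard error. Cis versus trans orientation is taken from the
glycosidic-bond direction proxy: the vectors from each ribose centroid to
its base-ring centroid point to the same side of the pair axis (*cis*) or
opposite sides (*trans*). A canonical pair is reported as
`cis WC/WC`; the sheared G·A pair — G N2 to A N7 plus A N6 to G N3 — is
`trans Sugar/Hoogsteen`. `detect_sheared_GA` filters classified pairs for
that signature and counts tandem occurrences (adjacent residue numbers on
both strands).

`superpose` is a from-scratch Kabsch fit (SVD of the covariance of
centered coordinates, with the reflection correction); collinear or
under-determined inputs are errors. `add_n6_methyl` places an sp²
CM6 carbon 1.45 Å from N6 in the base plane, in either the *syn* rotamer
(toward N1, i.e. toward the Watson-Crick edge) or *anti* rotamer (toward
the major groove). `clash_check` reports the minimal distance from the
methyl carbon to the partner's ribose atoms against a cutoff: in the
sheared geometry the N6 methyl must point at the partner guanine's ribose
(clash), while in a Watson-Crick A-U pair the *anti* rotamer sits in the
major groove (no clash). That asymmetry is the structural reading of why
N6-methylation blocks the sheared pair but tolerates canonical pairing.

## 6. Synthetic generators

Generators exist so that every analysis stage can be tested against
recorded ground truth; their defaults are idealizations, not fitted
values.

* `gen_snorna_set` plants an exact box C and box D with random flanks, an
  A1n adenine, a `-1n` base drawn from a configurable distribution
  (default all `C`), and a `-2n` base drawn from `A/C/U` so that a planted
  `-1n = C` always sits in a canonical DRACH context.
* `gen_alignment` mutates a generated root sequence row-wise with
  substitution and gap probabilities while pinning the `-1n` column to `C`
  with a configured probability; the realized fraction is recorded.
* `gen_modsites` places true sites exactly at mapped A1n genomic loci and
  decoys at least 5 nt away on the same chromosome.
* `gen_duplex_coords` builds an idealized A-form-like duplex of stacked
  canonical pairs and can replace one step with a constructed sheared G·A
  (the two bases counter-tilted by ±30° and rotated −60° to realize the
  trans Sugar/Hoogsteen bond lengths of 2.8 and 3.4 Å) or with a displaced
  N6-methyladenine (`resid 6MA`, *anti* CM6) that forms no base-base bond.
  Coordinates, residue numbering (chain B antiparallel, descending), and a
  per-step truth table are returned; optional Gaussian coordinate noise is
  applied before the truth is considered fixed.
* `gen_fret_curve` / `gen_itc_series` evaluate the exact models above and
  add Gaussian noise.

All generators run inside an isolated RNG stream derived from their
`seed`, so outputs are bit-reproducible and do not disturb the caller's
RNG state.

## 7. Pipeline

`run_kturn_pipeline` takes a list or YAML config naming a FASTA of
sequences and optional gene table, site table, Stockholm alignments, and
PDB structures. Stages run in order (scan, conservation, cross-reference,
structures); a stage failure is recorded in the summary with its message
and later stages still run. Artifacts (`scan.tsv`, `conservation.tsv`,
`crossref.tsv`, `structures.tsv`, `summary.json`) are written
deterministically, so repeated runs over the same inputs are
byte-identical.

## Limitations

* The pair classifier is tuned for the base-pair families exercised here
  (canonical WC, wobble, sheared G·A, unpaired); exotic families may
  land on the tie-breaking path.
* The duplex generator is an idealized ladder, not an A-form helix with
  correct twist; it is a test harness, not a modeling tool.
* The ITC model assumes one set of identical sites and ignores syringe
  heat effects beyond the displaced-volume correction.
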