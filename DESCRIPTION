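Package: snokturn
Title: Kink-Turn Annotation and N6-Methyladenine Analysis of Box C/D snoRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how N6-methylation of a conserved adenine
    controls the first step of box C/D snoRNP assembly. Locates box C/D and
    C'/D' elements in snoRNA sequences, assigns standard kink-turn (k-turn)
    position nomenclature and flags GAC/DRACH methylation targets at the A1n
    position; computes column and pair frequencies and -1n conservation over
    ortholog alignments; maps A1n positions to genomic coordinates and
    intersects them with m6A modification-site tables; fits the
    protein-induced folding FRET isotherm (quadratic tight-binding model) and
    the one-set-of-sites ITC model with derived thermodynamics; classifies
    base-pair geometry from 3D coordinates (hydrogen-bond detection,
    Leontis-Westhof edge and cis/trans assignment, sheared trans
    sugar-Hoogsteen G.A detection, N6-methyl placement with clash checking,
    Kabsch superposition); and generates synthetic inputs with recorded ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
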