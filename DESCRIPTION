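Package: venomlib
Title: Design and Quality Control of Recombinant Disulphide-Rich Peptide
    Expression Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building large Escherichia coli expression libraries
    of disulphide-rich (venom-type) peptides in silico: codon-optimized
    synthetic gene design under Codon Adaptation Index, GC-content and
    sequence-run constraints; tiling of genes into PCR-assembly
    oligonucleotides with in silico reassembly checks; assembly and
    annotation of periplasmic carrier fusion constructs; mass-spectrometry
    quality control of oxidation states via disulphide mass ladders and
    theoretical isotope patterns; concentration-based triage of purified
    peptides into normalized 96-well screening banks; and simulation of
    gene-synthesis error spectra with sequential colony screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
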