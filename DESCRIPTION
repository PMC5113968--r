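Package: cmtools
Title: Comparative Modeling Input Preparation and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing and validating the inputs of template-based
    protein structure modeling, and for benchmarking the models it produces.
    Parses PDB coordinate files into residue-level models that distinguish
    observed, missing (REMARK 465) and chemically modified (MODRES) residues
    and HETATM ligands; parses template-search reports (BLAST XML and HHsearch
    hhr) into a uniform hit table; trims, validates and bins target-template
    alignments by sequence identity; renders MODELLER-dialect PIR alignment
    files including ligand grafting with '.' records; computes rigid-body
    superposition (Kabsch) and the model-quality scores RMSD, TM-score, GDT-HA
    and lDDT; and runs a filter-based benchmark protocol (bin consistency,
    target coverage, template-target RMSD outlier removal) over synthetic
    fixture sets generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
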