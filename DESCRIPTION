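Package: glycobap
Title: Glycan Topology Compiler and Stereochemistry Validator for
    AlphaFold 3 Covalent-Ligand Input
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compiles glycan topologies (IUPAC-condensed text or programmatic
    graphs) into stereochemically unambiguous AlphaFold 3 input JSON using
    Chemical Component Dictionary (CCD) monosaccharide codes joined by
    explicit bondedAtomPairs, including leaving-atom remediation through
    edited chemical components (userCCD).  Also validates predicted
    glycoconjugate structures: anomeric configuration, epimeric
    (axial/equatorial) orientation, Cremer-Pople ring puckering, valence
    sanity, glycosidic torsions, and superposition RMSD against reference
    structures with iterative outlier rejection.  A synthetic coordinate
    builder generates ideal and deliberately corrupted test structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
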