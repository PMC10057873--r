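Package: PepScreen
Title: In Silico Digestion and PPARgamma-Antagonist Screening of Food Protein Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based simulation of simultaneous gastrointestinal proteolysis
    (pepsin, trypsin, chymotrypsin) of food proteins, enumeration of released
    peptide fragments with length-class statistics, bioaccessibility filtering
    to the passively absorbed 2-5 residue window, triage of peptide-docking
    affinity scores, sequence-derived physicochemical properties (elemental
    formula, average molecular weight, hydrogen-bond donor and acceptor
    counts, additive lipophilicity estimate), Lipinski rule-of-five
    drug-likeness verdicts, and geometric hydrogen-bond contact analysis of
    docked poses against a receptor hotspot residue set. Ships the rice
    prolamin and glutelin storage-protein fixtures and a synthetic-data
    module (random proteins with controlled composition, coordinate sets
    with planted hydrogen bonds) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Cheminformatics, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PepScreen-package.R'
    'dockprep.R'
    'pepchem.R'
    'proteolysis.R'
    'screening.R'
    'sequences.R'
    'synthdata.R'
    'utils.R'
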