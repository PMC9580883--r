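Package: pcpinet
Title: Phytochemical-Protein Interaction Networks with Simulated
    Glycoside Metabolism and Docking-Based Confidence Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for predicting and visualizing the cellular action
    of a medicinal plant against a disease via network pharmacology.
    Compiles a ligand registry from SMILES with canonicalization,
    deduplication and simulated hydrolysis of O-glycosides into aglycones;
    ingests reverse-screening target-prediction tables, causal
    protein-protein interaction tables and ADME property tables; filters
    predicted targets to a disease pathway by hypergeometric
    over-representation with Benjamini-Hochberg adjustment; assembles a
    typed, directed ligand-protein-protein network annotated with
    subcellular compartments, pharmacokinetic attributes and protein
    function; calibrates docking-energy confidence cutoffs and prediction
    probability confidence regions against docking results; and exports
    styled networks with a compartment-box cell layout to GraphML, JSON
    and CSV. A deterministic fixture generator produces complete toy
    input bundles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
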