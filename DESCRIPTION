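Package: binderkit
Title: Geometric Residue Codec, Diffusion Schedules and Quality-Diversity
    Triage for Protein Binder Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the non-neural computational core of all-atom
    diffusion-based protein binder design: an all-atom structure model with
    PDB input/output and tokenization; a geometric codec that encodes amino
    acid identity through the placement of virtual atoms on backbone anchors
    in a fixed 14-slot residue block; the EDM diffusion mathematics (forward
    process, preconditioning, training losses, noise schedules including a
    dilated time schedule, and a stochastic sampler exercisable with analytic
    denoisers); a YAML design-specification language with conditioning
    featurization; physics-based interface analysis metrics (hydrogen bonds,
    salt bridges, buried surface area, hydrophobic patches, solubility);
    and worst-rank quality aggregation with greedy quality-diversity
    candidate selection and Vendi-score diversity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
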