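Package: SeqIsoTrim
Title: Sequential Isosurface Trimming and Morphometric Analysis of Fossil Micro-CT Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing skeletal surfaces from noisy micro-CT
    scans of compacted fossils by Sequential Isosurface Trimming: extraction
    of isosurface meshes at many gray levels, removal of axis-aligned streak
    artifact components, pruning of redundant surfaces keeping the lowest
    gray level, merging, and ambient-occlusion culling of concealed faces.
    Includes a ground-truthed synthetic CT phantom generator for validating
    every pipeline stage, a constraint-based bilateral jaw-pose solver,
    Massare feeding-guild morphometrics (crown shape index, relative tooth
    size), and ancestral-state reconstruction of an ordered multistate
    character by Sankoff parsimony (with MPR state sets and origin-count
    ranges) and the equal-rates Mk likelihood model (marginal
    reconstructions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
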