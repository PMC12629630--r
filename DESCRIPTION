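Package: MCwound
Title: Structure-Based Metacaspase Substrate Screening and Wound-Response
    Transcriptome Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two linked analyses of type II plant metacaspases in
    the wounding response. First, a structure-based substrate screen that
    evaluates predicted enzyme-propeptide complexes with three sequential
    filters (inter-chain van der Waals clash count, buried interface area
    from a Shrake-Rupley solvent-accessible surface area implementation, and
    catalytic thiol-to-substrate proximity) and ranks candidate Arg/Lys P1
    cleavage sites. Second, a transcriptome dependence classifier that
    partitions differentially expressed genes across wild-type and
    metacaspase-mutant genotypes into Venn dependence classes, Pep1
    responsiveness groups and marker groups. Synthetic structure and
    differential-expression generators with independent oracles make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
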