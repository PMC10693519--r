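Package: seizurescope
Title: Seizure-Liability Screening: Pharmacovigilance Signals and Receptor
    Subunit Conservation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale pipeline for two computational procedures used in
    GABA-A receptor seizure-liability screening. The pharmacovigilance side
    tabulates drug-by-adverse-event 2x2 contingency counts from spontaneous
    report tables, computes disproportionality statistics (proportional
    reporting ratio, shrinkage information component with its 95 percent
    credibility lower bound), applies standard retention criteria, restricts
    signals to a seizure term group and summarizes per-drug adverse-event
    burden and pool-share rankings. The conservation side builds a linearly
    normalized substitution matrix from BLOSUM90 with explicit gap scores,
    scores aligned non-human receptor-subunit orthologs position-by-position
    against the human reference, maps alignment columns onto a cys-loop
    anchored extracellular-domain coordinate system and summarizes
    conservation per annotated segment. A synthetic-data module generates
    spontaneous-report tables with multiplicatively spiked drug-event pairs
    and ortholog alignments with controlled per-segment divergence, each with
    ground truth for recovery tests, and a run-all driver joins both
    pipelines with external in-silico hit flags into a red-flag report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
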