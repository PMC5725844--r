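Package: scratchsim
Title: Rule-Based Simulation of Glioblastoma Cell Motility and Proliferation in a Scratch Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seedable, scriptable agent-based simulator of the in vitro
    scratch (wound-healing) assay for glioblastoma cell lines such as T98G.
    Cells at the scratch edge cleave an adhesion molecule and release its
    ectodomain, which stimulates motility and proliferation through two
    receptor pathways (integrin, FGFR) converging on FAK; each pathway can be
    inhibited by a user-set fraction, scaling both speed and cell-cycle
    progression. The package provides the full rule set (density-directed and
    random movement, ligand release and diffusion, spring-like cell-cell
    adhesion, a four-phase cell cycle with mitosis), per-tick monitor metrics
    with CSV export, interval-resampled motility averages, scenario presets,
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
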