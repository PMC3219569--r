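Package: mtfba
Title: Multi-Tissue Constraint-Based Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("mtfba", "developers", email = "mtfba@example.org", role = c("aut", "cre"))
Description: Tools for assembling tissue-specific genome-scale metabolic
    models into a single multi-tissue model connected through a blood
    compartment, and for simulating integrated metabolic states with
    constraint-based methods: flux balance analysis (FBA), flux variability
    analysis (FVA) with flux-span metrics and loop exclusion, lexicographic
    multi-objective optimization, and carbon-fate accounting. Includes an
    expression-driven model extraction step (GIMME) with FVA-based
    differential reaction-activity comparison between conditions, a model
    quality-control suite (elemental and charge balance, futile energy
    cycles, dead-end metabolites, functional validation tests), readers and
    writers for SBML and a plain tab-delimited model format, and a
    deterministic generator of small proton-explicit toy tissue models with
    hand-derivable optima. A self-contained bounded-variable simplex solver
    backs all linear programs so the package has no external solver
    dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
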