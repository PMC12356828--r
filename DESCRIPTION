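Package: cnstriage
Title: Integrative Triage and Ranking of CNS Drug-Repurposing Candidates
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative drug-repurposing analysis pipeline for
    central-nervous-system targets. Calls differentially active
    transcriptional regulators from activity matrices (cluster-wise Welch
    statistics combined by Stouffer's method with Benjamini-Hochberg FDR
    control and an association-score gate), triages docking-affinity
    matrices against a kcal/mol threshold, profiles blood-brain-barrier
    suitability from physicochemical descriptors (Clark logBB model,
    permeability bins, P-glycoprotein efflux rule, safety and lipophilicity
    windows), computes molecular-dynamics stability metrics from scratch
    (Kabsch superposition, RMSD series, Shrake-Rupley solvent-accessible
    surface area, geometric hydrogen-bond detection), and combines all
    evidence into a gated, ranked candidate report. Ships a synthetic-data
    module that generates every input with planted signal so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
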