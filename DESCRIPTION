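Package: avnsim
Title: Compact Dual-Pathway Atrioventricular Node Conduction Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact 33-cell model of the rabbit atrioventricular (AV) node
    built from Aliev-Panfilov two-variable cells, with fast and slow conduction
    pathways, primary (sinus) and subsidiary pacemaking, graded and
    direction-asymmetric intercellular coupling, and pathway ablation
    interventions.  Ships stimulation protocols (S1S2 premature stimulation,
    random atrial-fibrillation pacing, regular atrial-flutter pacing), an
    adaptive Runge-Kutta (2,3) integration engine with event-exact stimulus
    delivery, an analysis layer (activation detection, conduction and
    refractory curves, ERPN/FRPN estimation, reentry and Wenckebach
    classification, His-His statistics), and Lewis ladder-diagram
    visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
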