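Package: gcell
Title: Compartmental Modelling Workbench for Dentate Granule Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained compartmental modelling workbench for dentate
    gyrus granule cells (GCs). Reads, validates and measures neuronal
    morphologies in SWC format; generates synthetic GC dendritic trees by a
    cone-sampling plus minimum-spanning-tree procedure with pruning,
    stretching, taper and jitter; declares region-specific ion channel models
    (Kir2, K2P, Kv, Nav, Cav, HCN, BK, SK) with per-layer conductance
    densities and named multiplicative variants (barium blockade, epilepsy,
    Kv1.1 overexpression, young adult-born GC, rat Kir adjustment);
    discretizes trees into an electrical mesh and integrates the cable
    equation with Hodgkin-Huxley and Markov channel kinetics, calcium
    dynamics, synapses and electrodes using an implicit Hines-ordered solver;
    ships the standard current- and voltage-clamp protocol battery (I-V, F-I,
    backpropagating action potentials, calcium transients, synaptic drive,
    sensitivity analysis) and extracts the canonical electrophysiology
    features (input resistance, capacitance, membrane time constant,
    rheobase, action potential threshold, amplitude, width, fast
    afterhyperpolarization, interspike-interval adaptation, Kir slope
    conductance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
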