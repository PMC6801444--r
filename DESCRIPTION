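Package: chiradsorb
Title: Chirality-Dependent Peptide-Membrane Adsorption Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chirality-dependent adsorption kinetics of
    amphipathic helical peptide enantiomers on lipid bilayers. Provides
    first-passage-time survival analysis with censored maximum-likelihood
    fitting of exponential, two-exponential mixture and gamma models;
    umbrella-sampling reweighting (WHAM and MBAR) into two-dimensional
    potentials of mean force over the insertion depth and helix rotation
    angle, with minimax-path barrier location; rotation-resolved lipid
    contact statistics including the weighted rotation score, the
    descending/ascending lipid census and side-switch counting; tryptophan
    indole orientation and head-group contact statistics; and a synthetic
    data module (ideal helix builder, pseudo-bilayer, overdamped Langevin
    traces on reference free-energy surfaces, Metropolis umbrella sampler,
    Poisson contact fixtures) that generates all inputs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    survival,
    bio3d,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
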