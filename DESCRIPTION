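Package: raddyn
Title: Tree-Accelerated Molecular Dynamics and Monte Carlo Simulation of
    X-Ray-Driven Ionization Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the ionization dynamics of atomic assemblies exposed
    to intense femtosecond X-ray free-electron-laser pulses.  All atoms,
    ions and quasi-free electrons are classical particles; each timestep
    executes four blocks in sequence: electron-ion recombination, secondary
    (impact) ionization, Monte-Carlo sampling of atomic processes
    (photoionization, Auger decay, fluorescence) from per-element rate
    tables, and velocity-Verlet propagation.  Both the long-range Coulomb
    interaction (Barnes-Hut multipole solver with opening-angle control)
    and the secondary-ionization neighbor search (linear oct-tree with
    depth-dependent bit-interleaved box identifiers) ship in interchangeable
    brute-force and tree-based implementations whose outputs are verified
    to be bit-wise identical for the ionization blocks, and built-in
    pair-evaluation counters make the O(N^2) versus O(N log N) complexity
    claims testable without wall-clock timing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
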