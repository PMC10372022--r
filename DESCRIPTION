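Package: krillflow
Title: Lagrangian Krill Connectivity with Diel Vertical Migration in
    Synthetic Shelf Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the dispersal and regional connectivity of Antarctic
    krill (Euphausia superba) along a West Antarctic Peninsula-like shelf.
    Generates idealized, divergence-free, multi-season gridded velocity
    fields with persistent circulation features (loop currents, a
    shelf-break jet, cross-shelf channels), advects particle proxies for
    krill with a compiled 4th-order Runge-Kutta kernel, adds diel vertical
    migration keyed to local solar elevation plus a gradient-corrected
    vertical random walk, builds penguin-colony-based study regions on a
    40 km cell lattice, and reduces trajectories to origin-destination
    connectivity matrices, transit and residence times, current-rose
    statistics, rank-based regional comparisons, and correlations with
    penguin colony sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ncdf4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
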