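Package: caburst
Title: Calcium-Modulated Bursting in Inhibitory Networks: Continuous
    Simulation and Discrete-Map Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates small excitatory-inhibitory integrate-and-fire
    networks in which a slow calcium-gated potassium (sAHP) current
    makes inhibitory cells alternate in firing bursts, and implements
    the analytic discrete-map reduction of those dynamics: a
    closed-form formula for the number of spikes per burst (NSPB) as a
    function of burst-initial calcium, the two-cell burst map and its
    fixed points with a stability test, the generalization to m+1
    inhibitory cells with s-periodic orbits, and parameter-sweep and
    bifurcation tools that compare the map against the continuous
    system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
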