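Package: lysochaos
Title: Chaotic Coexistence of Temperate and Obligate Lytic Bacteriophage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population dynamics of communities of temperate and
    obligate lytic bacteriophage preying on a shared bacterial host through
    their lysogens. Phage strains are organized into superinfection-immunity
    classes and distinguished by their lysogeny fraction. The package
    integrates the community ordinary differential equations in log-density
    coordinates over thousands of bacterial generations and many decades of
    dynamic range, provides the model's closed-form results (the homeostatic
    phage-to-lysogen ratio and the symmetric fixed point), estimates the
    largest Lyapunov exponent to diagnose chaos, classifies ecological
    outcomes (coexistence, extinction, fixed point), and ships scripted
    scenario runners for pairwise competition, lytic invasion, multi-strain
    bunching, and sweeps over the number of immunity classes. Mechanistic
    model extensions (sensitive bacteria, double lysogens, finite lysis time,
    coinfection-induced lysogeny, parameter heterogeneity) share the same
    integrator and analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
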