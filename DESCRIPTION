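Package: pnwave
Title: Excitable Reaction-Diffusion Models of the Drosophila Proneural Wave
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the proneural wave in the
    Drosophila optic lobe, modelled as an excitable reaction-diffusion system
    on cellular lattices. Implements a hierarchy of models: a single-component
    bistable front of EGFR signalling, a two-component excitable pulse of EGFR
    signalling and proneural (L'sc) expression, and an integrated lattice model
    coupling EGFR, L'sc, Delta-Notch signalling and an irreversible
    neuroepithelium-to-neuroblast cell-state transition. Provides hexagonal and
    one-dimensional cell lattices with a discrete diffusion operator,
    deterministic and stochastic (Euler-Maruyama) time integration, in-silico
    mutant and transgenic clones, wavefront and transition-zone observables, a
    neighbour-correlation index for lateral-inhibition (salt-and-pepper)
    patterns, Morris elementary-effects sensitivity screening of wave speed and
    zone width, and a two-cell Delta-Notch phase diagram for the occurrence of
    lateral inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
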