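Package: vesselheal
Title: Constrained-Mixture Simulation of Arterial Clamping Injury and Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of arterial clamping injury and long-term
    healing on a reduced thin-walled vessel. Implements a constrained-mixture
    constitutive model (Gasser-Ogden-Holzapfel passive behaviour with collagen
    cohort bookkeeping and deposition prestretch, plus an active smooth-muscle
    energy), continuum damage laws for acute clamp overstretch of contractile
    smooth muscle cells, collagen and endothelium, day-scale remodeling laws
    (collagen cohort turnover, smooth muscle phenotype switching, logistic
    endothelial healing, inflammation), and a vasoactive-agent-dependent
    contraction model built on Hai-Murphy four-state crossbridge kinetics with
    filament sliding. A five-step protocol (homeostatic prestress, clamping,
    healing, excision, virtual wire myograph) reproduces acute and one-month
    healed vessel states and their dose-response behaviour under
    phenylephrine, acetylcholine and nitric oxide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
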