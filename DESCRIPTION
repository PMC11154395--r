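Package: tktdcu
Title: Toxicokinetic-Toxicodynamic Modelling of Copper Accumulation and
    Toxicity in Bivalves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mechanistic analysis of waterborne copper uptake,
    elimination and lethality in filter-feeding bivalves. Implements a
    one-compartment toxicokinetic model with closed-form solutions under
    constant and piecewise-linear exposure, a threshold-hazard
    (stochastic-death) toxicodynamic survival model, stable-isotope tracer
    background correction for enriched 65Cu exposures,
    Levenberg-Marquardt nonlinear least-squares estimation of uptake and
    elimination rate constants (with a shared elimination rate across
    treatments), internal threshold and killing rate, Michaelis-Menten
    saturation of uptake versus exposure concentration, model-based and
    probit LC50 estimation, and a seeded generator of virtual experiments
    for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
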