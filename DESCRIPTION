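Package: coagsim
Title: Coagulation-Network Simulation of INR and aPTT for Anticoagulant Therapy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative systems pharmacology simulator of the human
    coagulation cascade for predicting the clinical biomarkers INR (warfarin,
    phenprocoumon) and aPTT (rivaroxaban) in virtual patients stratified by
    CYP2C9 and VKORC1 genotype. The cascade is defined as data in a versioned
    parameter table (turnover, Michaelis-Menten activation, 1:1 complex
    formation), compiled into a stiff ODE system, and chained from in-vivo
    steady-state dosing simulations into in-silico prothrombin-time and
    activated-partial-thromboplastin-time clotting assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
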