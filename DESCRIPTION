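Package: prevalink
Title: Registry-Linked Prevalence Estimation with Probabilistic Record
    Linkage and Bayesian Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the prevalence of a condition recorded in
    a school special-education registry and correcting it with linked
    clinical records. Provides a synthetic registry and
    electronic-health-record generator with known ground truth, crude and
    directly age-sex standardized prevalence with gamma (Fay-Feuer)
    confidence limits, Fellegi-Sunter probabilistic record linkage with
    blocking and bijective assignment, prevalence-ratio estimation by
    Poisson regression with robust (sandwich) variance, and a Bayesian
    random-effects model with bounded uniform priors, fit by a
    Metropolis-within-Gibbs sampler, that projects clinically corrected
    prevalence across health services and quantifies unmet
    special-education need.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
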