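Package: dietwebs
Title: Season-Wide Food-Web Specialization from Molecular Gut-Content Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds predator-by-prey interaction webs from individual-level
    molecular gut-content detections collected on a replicated field design,
    quantifies network-level specialization (H2', the standardized
    two-dimensional Shannon entropy of a bipartite web), compares each web
    against a permutation null via a Cohen's-d standardized effect size, and
    computes Shannon-Weaver diversity of predator and prey communities per
    sampling unit (with aphid tiller-count substitution). Ships a synthetic
    data generator emulating the two-year, multi-field, biweekly-session
    study design, with a controllable seasonal specialization profile, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
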