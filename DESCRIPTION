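Package: reprocomp
Title: Reproductive Compensation and Mutation-Selection Balance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic population-genetic models of Fisher's reproductive
    compensation: brood-structured genotype-frequency recursions in which the
    death of offspring frees resources that raise the survival of their full
    siblings (competitive release). Computes equilibrium frequencies of
    semidominant deleterious mutations at autosomal, sex-linked, and
    sexually dimorphic sex-linked loci, the fold increase in equilibrium
    frequency attributable to compensation, closed-form reference results
    from classical mutation-selection balance theory, and parameter-grid
    sweeps with regression summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
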