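Package: themedyn
Title: Linking Reused Sequence Segments to Protein Dynamic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the correspondence between evolutionarily reused
    sequence segments ("themes") and the dynamic elements of a protein
    domain's slow collective motions. Builds a Gaussian network model from
    a C-alpha trace, segments each slow mode into dynamic elements via a
    sign-partition and minimum-length merge rule, enumerates theme
    combinations that tile the domain under overlap and gap constraints,
    and scores theme-element correspondence with adjusted and standardized
    mutual information under the fixed-marginal hypergeometric null, plus
    Monte-Carlo p-values from random segment-set nulls. Includes a
    synthetic-domain generator (helix bundles, collapsed walks) so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
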