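Package: spacerace
Title: CRISPR-Phage Coevolution Analysis from Infection Matrices, Spacers and
    Protospacer Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing host-parasite coevolution between a
    CRISPR-immune bacterium and its lytic phage in serial-transfer experiments.
    Includes a genotype-resolved serial-transfer simulator (spacer acquisition
    versus protospacer/PAM escape mutation), a mechanistic infection-prediction
    rule, infectivity/resistance range summaries with bootstrap confidence
    intervals, time-shift (past/present/future) scoring, a balanced two-way
    ANOVA mean-square decomposition separating arms-race from
    fluctuating-selection dynamics, spacer diversity metrics (pairwise
    difference, genotype richness), SNP calling and seed/PAM classification,
    and predicted-versus-measured contingency analysis. All user-facing
    functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
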