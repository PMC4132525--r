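Package: mokkensep
Title: Nonparametric Item Response Theory Scaling of Household
    Socioeconomic Position
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs asset-based measures of household socioeconomic
    position from dichotomous ownership items using Mokken scale analysis:
    Loevinger scalability coefficients (pairwise, per item, per scale, and
    on the transposed response matrix), the automated item selection
    procedure, restscore checks of monotonicity and invariant item
    ordering with iterative removal of offending items, and the unweighted
    sum score with wealth quintiles. A contrasting principal-component
    index built on the tetrachoric (polychoric) correlation matrix,
    weighted Cronbach's alpha reliability, and comparisons against
    log household expenditure complete the pipeline. A synthetic household
    generator with a two-parameter logistic response model supports
    testing every stage without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
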