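Package: glyre
Title: Regular Expressions for Branched Glycan Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A feature-complete regular-expression engine for branched
    glycans. Parses IUPAC-condensed glycan strings into rooted trees with
    alternating monosaccharide and linkage nodes, parses a glyco-regex
    pattern dialect (wildcards, linkage ambiguity, negation, quantifiers
    with greedy and lazy execution, lookahead/lookbehind, branch groups),
    and returns matches as connected node sets together with their
    serialized sub-glycans. Includes application utilities such as
    extracting the alpha1-6 branch of N-glycans and building motif-count
    matrices, a seedable synthetic glycan generator, and an independent
    brute-force matching oracle for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
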