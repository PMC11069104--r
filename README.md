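# glyre — regular expressions for branched glycan structures

Glycans are branched polymers of monosaccharides; their biology is driven
by motifs — short sub-structures such as sialyl Lewis x,
Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc — whose position within the larger
structure matters. Questions like *"what sits on the α1-6 arm of this
N-glycan?"* are hard to automate with text tools because one branched
structure admits many string spellings. glyre answers them on the graph:
it parses IUPAC-condensed glycans into rooted trees with alternating
monosaccharide and linkage nodes, compiles a regex-like pattern dialect
(wildcards, linkage ambiguity `b3/4`, negation `!Fuc`, quantifiers
`? * + {n,m}` with greedy/lazy execution, branch groups `(Fuca3)`,
lookahead/lookbehind), and returns every match as a connected set of node
indices plus its serialized sub-glycan.

It is aimed at glycoinformaticians who need motif annotation, branch
extraction, or motif-count matrices as input to enrichment and
differential-abundance analyses (the statistics themselves are out of
scope — `count_matches()` emits the table those tools consume).

## Worked example

```r
library(glyre)

slex <- "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc"   # sialyl Lewis x

get_match("Fuca3GlcNAc", slex)
#> <glyre_match> Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc
#>   [1] nodes {5,6,7}  Fuca1-3GlcNAc

get_match("(?<=Neu5Aca3)Galb4(Fuca3)GlcNAc", slex)
#> <glyre_match> Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc
#>   [1] nodes {3,4,5,6,7}  Fuca1-3(Galb1-4)GlcNAc
```

Node indices are 1-based token positions in the canonical string:
Neu5Ac = 1, a2-3 = 2, Gal = 3, b1-4 = 4, Fuc = 5, a1-3 = 6, GlcNAc = 7.
The first query finds the fucosylated GlcNAc (nodes 5–7). The lookbehind
variant additionally *requires* the α2-3 sialylated galactose context but
excludes its nodes (1 and 2) from the reported match.

Branch extraction on a biantennary N-glycan — the pattern captures the
α1-6 arm and asserts the trimannosyl-chitobiose core in a lookahead:

```r
bi <- paste0("Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
             "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3)",
             "Manb1-4GlcNAcb1-4GlcNAc")
extract_branch(bi, "Neu5Aca6Galb4GlcNAcb2Mana6(?=Manb4GlcNAcb4GlcNAc)")
#> [1] "Neu5Aca2-6Galb1-4GlcNAcb1-2Man"
```

Note `Neu5Aca6` resolves to `a2-6` automatically: sialic acids donate
from C2. Greedy vs lazy on tandem LacNAc repeats:

```r
poly <- "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Gal"
trace_match(poly, "(Galb4GlcNAcb3)+")    # greedy: one 3-unit match, nodes 1-12
trace_match(poly, "(Galb4GlcNAcb3)+?")   # lazy: three 1-unit matches
```

A command-line interface ships in `exec/glyre`
(`match`, `extract`, `count`, `simulate`, `explain`); see the vignette
(`vignettes/glyco-regex.Rmd`) for the full pattern grammar and matching
semantics.

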