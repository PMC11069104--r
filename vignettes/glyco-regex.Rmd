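---
title: "Glyco-regex: pattern matching on glycan graphs"
author: "glyre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glyco-regex: pattern matching on glycan graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Why a regex engine for glycans

Glycans are branched polymers of monosaccharides whose biology is carried
by motifs — short sub-structures such as sialyl Lewis x,
Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc — whose *position* within the larger
structure matters: a terminal motif is recognized by lectins that ignore
the internal form, and the same epitope behaves differently on the α1-3
and α1-6 arms of an N-glycan. Text regular expressions cannot answer these
questions reliably, because the same branched structure admits several
equally valid string spellings. glyre therefore matches patterns against
the *graph* of a glycan, never against its string: it parses
IUPAC-condensed text into a rooted tree, compiles a regex-like pattern
dialect, and returns matches as connected node sets.

## The glycan graph

`parse_iupac()` builds a rooted tree in which monosaccharide and linkage
nodes strictly alternate. Linkages are nodes, not edge labels, so that a
match (or a lookaround exclusion) can refer to them by index. Edges point
child → parent toward the reducing-end residue (the root). A glycan with
*k* residues always has 2*k*−1 nodes.

Node indices are **1-based** (the natural R convention) and equal the
token position, left to right, in the canonical serialized string. For
`Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc`: Neu5Ac = 1, a2-3 = 2, Gal = 3,
b1-4 = 4, Fuc = 5, a1-3 = 6, GlcNAc = 7.

**Canonical branch order.** IUPAC-condensed does not fix which branch is
written outside the parentheses, and round-trip testing needs a
deterministic choice. glyre's own convention: at every branch point the
longest branch (most residues on its longest path) is the main chain; ties
break by lowest acceptor carbon, then lexicographically by residue token.
`to_string()` always emits this form, and `to_string(parse_iupac(x))` is
idempotent. Full linkage tokens (`a1-3`, not `a3`) are always emitted so
that every serialized sub-glycan re-parses.

Both the Unicode (α/β, en-dash) and ASCII (a/b, hyphen) dialects are
accepted on input; output is ASCII unless `dialect = "unicode"` is asked
for. The fully unknown linkage is written `?1-?` (the conventional token)
and matches anything in both directions.

## The pattern dialect

Patterns read non-reducing → reducing, like the glycan strings themselves.
Whitespace is insignificant.

| construct | meaning |
|---|---|
| `Man`, `GlcNAc` | exact residue |
| `.` or `Monosaccharide` | any single residue |
| `!Fuc` | any single residue that is not Fuc (positional negation) |
| `Gal\|GalNAc` | residue alternation |
| `Mana6` | linkage shorthand; donor carbon inferred (`a1-6`) |
| `Neu5Aca3` | C2 donors inferred for ulosonic acids (`a2-3`) |
| `Galb3/4` | linkage alternation (`b1-3` or `b1-4`) |
| `Gal?1-?Glc` | explicit full-form linkage, `?` components match anything |
| `(Fuca3)GlcNAc` | branch group: Fuc must hang off the GlcNAc |
| `X?  X*  X+  X{n}  X{n,m}  X{n,}` | quantifiers on a residue or group |
| `+?` etc. | lazy variant of any quantifier |
| `(?=core)` | lookahead, only at the reducing end |
| `(?<=context)` | lookbehind, only at the non-reducing end |

Design choices where the dialect was genuinely open:

* **Quantified groups are chain repeats.** `(Galb4GlcNAcb3){1,3}` matches
  one to three *tandem* LacNAc units along a chain. An unquantified
  `( … )` group directly before a residue is a glycan branch, exactly as
  in IUPAC-condensed; the two-character prefixes `(?=`/`(?<=` mark
  lookaround. A linkage may not follow a quantifier (`Man*a3` is an
  error); write it inside the unit (`(Mana3)*`).
* **Negation is positional.** `!Fuc` matches exactly one residue whose
  token differs from Fuc; it does not assert that Fuc is absent elsewhere
  in the glycan. Global absence composes from a second query.
* **Lookaround placement.** Interior lookaround has no obvious semantics
  on a tree, so lookbehind is restricted to the left (non-reducing) end
  and lookahead to the right (reducing) end.
* **Unknown components match both ways.** A `?` anomer/carbon in either
  the glycan or the pattern is a wildcard; this is the least-surprise
  reading of structural ambiguity.

`parse_pattern()` yields the element AST (`glyre explain PATTERN` prints
it); `expand_quantified()` turns a quantified element into its
(substructure : allowed counts) pair, the form the engine consumes.

## Matching semantics

`trace_match()` compiles the pattern into a chain of steps, materializes
every admissible quantifier count — unbounded quantifiers are capped at
the glycan's residue count, since no repeat unit can occur more often —
and searches each resulting plain chain by recursive descent from the
reducing end of the pattern, so matches are connected subtrees by
construction. Each residue step owns its monosaccharide node plus, when a
linkage is specified or another step follows, the linkage node joining it
rootward; stitched segments therefore include the intervening linkage
nodes. Branch groups must embed on *distinct* children of their anchor
residue; which branch the glycan string happened to spell as "main" is
irrelevant, because matching never sees the string.

* **All matches are returned**, overlapping ones included; deduplication
  is by node-set equality, and results are ordered by lowest node index
  (ties: larger match first). The engine is deterministic.
* **Greedy vs lazy.** Greedy (the default) keeps matches that are
  count-maximal — no valid extension exists, operationally: not a strict
  subset of another match. Lazy keeps count-minimal matches. A lazy glyph
  anywhere in the pattern (`+?`) switches the whole selection to lazy;
  per-element mixtures of greedy and lazy are not given finer semantics.
* **Lookaround** must match for the pattern to match, but its node
  indices (including the linkage joining lookbehind context to the
  match) are excluded from the reported sets.
* **Empty matches are dropped.** A pattern whose every element admits
  count zero could match nothing at all; a reported match must cover at
  least one node.

## Branch extraction and count tables

`extract_branch()` serializes each match; a linkage node on the rootward
boundary of a match (e.g. the α1-6 joining an arm to the N-glycan core) is
part of the node set — so that the two arm queries plus the core partition
the glycan exactly — but is cut from the serialized string, which must
begin and end on monosaccharides to be valid IUPAC-condensed.

```r
bi <- paste0("Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
             "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3)",
             "Manb1-4GlcNAcb1-4GlcNAc")
extract_branch(bi, "Neu5Aca6Galb4GlcNAcb2Mana6(?=Manb4GlcNAcb4GlcNAc)")
#> [1] "Neu5Aca2-6Galb1-4GlcNAcb1-2Man"
```

`count_matches()` assembles the motif-count matrix (rows = glycans,
columns = queries, cells = number of distinct matches) that downstream
enrichment or differential-abundance analyses consume; those statistics
are deliberately out of scope here, and unparseable glycans become all-NA
rows reported via the `failures` attribute rather than being dropped.

## Synthetic glycans and the oracle

`generate_glycans()` draws random valid glycan trees: size uniform in
1..`max_residues` (default 10), residues from a nine-token mammalian-type
alphabet, linkages from {α,β} × {2,3,4,6} with distinct acceptor carbons
among siblings, donor carbon following the C1/C2 rule, a 5% default rate
of fully unknown linkages, and `branch_prob` (default 0.2) as the
per-attachment probability of starting a branch at an internal node
rather than elongating the chain tip. The same spec and seed reproduce
the same strings bit-exactly, and generation does not disturb the
caller's RNG stream. The generator emulates the *syntactic* variety of
real glycomes (branching, ambiguity, sialic-acid linkage chemistry); it
knows nothing of biosynthetic pathways, so passing tests speak to the
correctness of the matcher, not to biological plausibility of any corpus.

`brute_force_match()` is the independent oracle: it expands the AST into
explicit pattern-node tables and enumerates every injective assignment of
pattern nodes to glycan residues, checking labels, adjacency and linkages
by direct definition, then applies the same maximality/minimality rule.
It shares only the two parsers with the engine; expansion, search and
selection are implemented separately, which is what makes agreement
between the two meaningful. Being exponential, it refuses glycans above
14 residues.

The test suite checks engine–oracle equality on 500 seeded
(pattern, glycan) pairs for each of 14 grammar features (wildcard,
linkage alternation, negation, the six quantifier glyph families, lazy
variants, branch groups, lookahead, lookbehind) over glycans of up to 12
residues, plus serialization round-trips on 200 synthetic glycans — sizes
chosen so the whole suite runs in about a minute on one CPU while still
covering every feature combinatorially.

## Numerical and degenerate-input choices

* Quantifier expansion is exact, not heuristic; a safety cap (50,000
  expanded chains) guards against pathological patterns.
* A single-residue glycan is a one-node graph; a single-token subset
  serializes to that token alone.
* Two residue names written with no linkage between them are lexically a
  single unknown token; a vocabulary of common monosaccharide names is
  used to reject obvious concatenations ("GalGlcNAc") with a parse
  error, as truly novel residue names cannot be distinguished from typos.
* Parse errors are classed (`glyre_parse_error`) and carry the character
  offset of the offending token.

## Known limitations

* Only IUPAC-condensed input is parsed; WURCS, GlycoCT, Oxford and
  IUPAC-extended are out of scope.
* Composition-only or topology-unknown descriptors are not representable.
* No top-level sub-pattern alternation (`A|B` across whole chains), no
  backreferences, no named capture groups.
* No approximate or scored matching; a match either satisfies every
  constraint or is not reported.
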