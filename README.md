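# AmyloidPaths

Hexapeptides are a standard model system for protein amyloid formation,
and linear position-weight classifiers label each of the 20⁶ = 64,000,000
possible hexapeptides as *amyloidogenic* (aggregation-prone) or
*non-amyloidogenic*. AmyloidPaths is for peptide designers and sequence
analysts who want to move through hexapeptide sequence space one point
mutation at a time **without ever leaving a predicted class** — e.g. to
plan a synthesis series or a mutational trajectory whose every intermediate
is still predicted amyloidogenic.

## The model

A hexapeptide `x = (X₁,…,X₆)` gets the decision value

    A(x) = b + Σᵢ E[Xᵢ, i]

where `E` is a 20 × 6 **amyloid effect matrix** of per-residue,
per-position contributions and `b = 1.083` the intercept (both embedded,
exactly as published). `A(x) ≥ 0` predicts amyloidogenic, `A(x) < 0`
non-amyloidogenic.

Define the **mutation graph** on all hexapeptides with an edge between two
peptides iff they differ in exactly one position. Because `A` is a sum of
independent per-position terms, any two peptides of the same predicted
class can be joined by a path of length at most 6 — exactly their Hamming
distance, hence a shortest path outright — whose every node keeps the
class: climb from the first peptide to the coordinate-wise most (or, for
the non-amyloidogenic class, least) amyloidogenic combination of the two
(the *meet*), then descend to the second. Scores are monotone along each
leg, so no intermediate can cross the threshold. The package implements
the scoring, the per-position residue orderings and their max/min
operators, the two-leg construction, an independent BFS oracle over small
sub-lattices, and closed-form classification of wildcard patterns like
`CxFLWx`.

## Worked example

```r
library(AmyloidPaths)
m <- bapMatrix()                       # the published 20x6 matrix, b = 1.083

amyloidScore(m, c("YVSTSY", "ILVWIW", "CVFFFF"))
#> YVSTSY ILVWIW CVFFFF
#> -0.557  0.753  0.633
```

`YVSTSY` scores −0.557 (= −0.23 −0.14 −0.41 −0.23 −0.48 −0.15 + 1.083), so
it is predicted non-amyloidogenic; the other two are amyloidogenic.
Connect the two amyloidogenic peptides:

```r
connectPeptides(m, p1 = "CVFFFF", p2 = "LYCLCI")
#> PathReport (amyloidogenic): 6 edges, meet CYFLFI (legs 3 + 3)
#>   CVFFFF-CYFFFF-CYFLFF-CYFLFI-CYFLCI-CYCLCI-LYCLCI
#>   scores: 0.633 0.663 0.733 0.773 0.733 0.713 0.703
```

Six single-residue substitutions (the endpoints' Hamming distance — the
minimum possible), rising monotonically to the meet `CYFLFI` and falling
monotonically after it; every score stays ≥ 0, so every intermediate is
predicted amyloidogenic. Patterns work by closed-form extremization of the
same linear score:

```r
classifyPattern(m, "CxFLWx")
#> [1] "all_amyloidogenic"
patternExtremes(m, "CxFLWx")$min       # worst-scoring match, CKFLWP
#> [1] 0.063
countClass(m, "CxFLWx", "amyloidogenic")
#> [1] 400
```

All 400 hexapeptides matching `CxFLWx` are predicted amyloidogenic; the
worst of them still scores +0.063. A seeded verification run over random
same-class pairs confirms the path property wholesale:

```r
sampleVerify(m, nPairs = 200, seed = 42, cls = "non_amyloidogenic")
#> VerificationSummary: 200 pairs (seed 42), max path length 6, 0 class / 0 length violations
```

A command-line wrapper with `predict`, `score`, `order`, `neighbors`,
`path`, `verify`, `pattern` and `fixtures` subcommands ships at
`system.file("scripts", "bap-tool.R", package = "AmyloidPaths")`.

See the vignette (`vignettes/amyloid-mutation-paths.Rmd`) for the
construction's correctness argument, tie handling, the BFS oracle, and
known rounding sensitivities of the printed matrix.

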