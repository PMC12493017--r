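---
title: "Class-preserving mutation paths between hexapeptides"
author: "AmyloidPaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-preserving mutation paths between hexapeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmyloidPaths)
```

## The model

Short peptides of six residues (hexapeptides) are a standard model system
for studying amyloid formation — the aggregation of misfolded peptides into
cross-β fibrils.  There are $20^6 = 64{,}000{,}000$ hexapeptides over the 20
proteinogenic amino acids, and a family of sequence-based predictors labels
each of them *amyloidogenic* or *non-amyloidogenic*.

The predictor implemented here is a linear support-vector machine whose
decision value for a hexapeptide $x = (X_1,\dots,X_6)$ collapses, because
each residue contributes independently per position, to

$$A(x) \;=\; b + \sum_{i=1}^{6} E[X_i,\, i],$$

where $E$ is a $20 \times 6$ *amyloid effect matrix* of pre-computed
per-residue, per-position contributions and $b = 1.083$ is the intercept.
The class rule is the SVM sign rule with the boundary inclusive:
$A(x) \ge 0$ predicts amyloidogenic, $A(x) < 0$ non-amyloidogenic.  There is
no epsilon band around zero.

```{r}
m <- bapMatrix()
amyloidScore(m, c("YVSTSY", "ILVWIW"))
scoreBreakdown(m, "YVSTSY")
```

The embedded matrix is the published one, with cells printed to two
decimals and the intercept to three.  We treat those printed values as
exact.  The unrounded weights of the original predictor are not available,
so peptides with $|A| \lesssim 0.03$ (six cells each rounded by up to
0.005, plus the intercept) can legitimately disagree with the original
web-server implementation.  The package documents this sensitivity rather
than compensating for it; equality tests against printed three-decimal
values use a tolerance of $5\times10^{-4}$, half a unit of the printed
precision.

The matrix is parameterized by its number of columns, so every operation
generalizes to $k$-mers; 6 is the default everywhere.

## Per-position orderings and the max/min operators

Sorting each matrix column by decreasing contribution gives, per position,
a total order of the 20 residues from most to least amyloidogenic:

```{r}
o <- deriveOrdering(m)
rankTable(o)[1, ]
```

The orderings are **derived from the matrix, never hard-coded from the
printed ordering table**, because the printed table's row 4 is internally
inconsistent (it lists C twice and omits V, even though V has the largest
column-4 contribution, 0.14).  The printed rows are retained only as an
audit reference:

```{r}
audit <- compareToReference(o)
audit$duplicates
audit$missing
audit$mismatches
```

Ties (e.g. W and Y both contribute −0.06 at position 4) are broken by the
printed reference row where that row is a valid permutation, and
alphabetically otherwise.  This reproduces the published table wherever it
is self-consistent and is deterministic everywhere.  Tie direction can
never affect scores: `maxResidue()` / `minResidue()` satisfy non-strict
contribution inequalities by construction, which is all the path
construction needs.

## The mutation graph and the path construction

The mutation graph has the $20^6$ hexapeptides as vertices, with an edge
between two peptides iff they differ in exactly one position (Hamming
distance 1).  Every vertex has $6 \times 19 = 114$ neighbors.  The graph is
never materialized; all operations (`neighborPeptides()`, path legs, the
BFS sub-lattice) are local and on demand.

Because $A$ is a sum of independent per-position terms, replacing a residue
with an earlier-ranked one at its position never decreases $A$.  Two
consequences:

* **Monotone leg (easy case).**  If `end` dominates `start` coordinate-wise
  (every residue at or above `start`'s in its position's order), then
  substituting the differing positions one at a time — the package uses
  ascending position order — gives a path along which $A$ is monotone
  non-decreasing.  Any substitution order is monotone; fixing ascending
  order makes output reproducible.

* **Two-leg construction (general case).**  For any two amyloidogenic
  peptides $x, x'$, their coordinate-wise maximum (the *meet*, built with
  `maxResidue()` per position) dominates both, so $x \to \text{meet}$ and
  $x' \to \text{meet}$ are both monotone non-decreasing legs.  Joining leg 1
  with the reverse of leg 2 yields a path whose every node satisfies
  $A \ge \min(A(x), A(x'))\ge 0$: every intermediate is amyloidogenic.  For
  non-amyloidogenic pairs the symmetric construction through the
  coordinate-wise minimum keeps every node strictly below 0.

Since the meet's residue at each position equals the corresponding residue
of $x$ or $x'$, a position changed in leg 1 is never changed in leg 2; the
total edge count is exactly the Hamming distance of the endpoints — at most
6, and a globally shortest path even ignoring the class constraint.

```{r}
rep <- connectPeptides(m, o, "CVFFFF", "LYCLCI")
rep
```

Cross-class pairs are refused loudly (`connectPeptides()` errors, citing
both scores): the construction claims nothing about paths between an
amyloidogenic and a non-amyloidogenic peptide, and a best-effort path would
misrepresent that.

**Leg-2 substitution order.**  Two published example paths imply different
orders for leg 2: one is reproduced by building leg 2 from the second
endpoint toward the meet in ascending position order and reversing it
(the package default, `leg2Order = "from-endpoint"`), the other by
substituting ascending positions starting from the meet
(`leg2Order = "from-meet"`).  Monotonicity holds under any order, so both
are supported and neither is asserted as canonical.

## The BFS oracle

`bfsShortestClassPath()` is an independent check of the construction.  It
restricts the graph to the sub-lattice generated per position by the two
endpoints' and the meet's residues (at most $3^6 = 729$ nodes), removes
wrong-class nodes, and runs an unweighted shortest-path search (via
\pkg{igraph}).  The sub-lattice provably contains the constructed two-leg
path, so a finite BFS distance equal to the endpoint Hamming distance
certifies that the construction is optimal — the BFS never consults the
constructive code path.

## Wildcard patterns

A pattern such as `CxFLWx` fixes some positions and leaves others free
(`x` = all 20 residues; `[ILV]` = a restricted set).  Linearity again gives
a closed form: the extreme scores over all matching peptides are obtained
by choosing, independently per slot, a residue of extreme contribution.

```{r}
patternExtremes(m, "CxFLWx")
classifyPattern(m, "PxDxxx")
```

A pattern is *all-amyloidogenic* iff its minimum score is $\ge 0$ and
*all-non-amyloidogenic* iff its maximum is $< 0$, consistent with the
peptide-level threshold.  `countClass()` cross-checks by full enumeration
(capped at $10^7$ matches to prevent accidental 64M-peptide scans; the
closed form has no cap).

With the two-decimal printed matrix, several published pattern claims hold
only by thin margins (`FxFLFx` min $+0.013$, `PxDxxx` max $-0.027$,
`xxKxEx` max $-0.017$), and one — `xxPQxx`, whose maximum lands at $+0.003$
attained by `VIPQIV` — comes out *mixed* rather than all-non-amyloidogenic.
These margins are inside the rounding error of the printed cells;
presumably the original unrounded weights resolve them.  The package
reports what the printed matrix yields, flags extremes within 0.03 of the
threshold as rounding-sensitive, and does not adjudicate.

## Synthetic fixtures and what the tests show

`makeFixtures()` draws seeded uniform random peptides and, optionally, a
random effect matrix with contributions uniform on $[-0.6, 0.3]$ (the span
of the published matrix) and the intercept set to minus the median raw
score of a seeded 1000-peptide sample, so both predicted classes are
non-empty.  Random matrices exercise the construction's *generality*: the
class-preserving shortest-path property depends only on the classifier
being linear with independent per-position terms, not on the published
weights — the test suite re-verifies all path invariants on 20 such
matrices.

Verification (`sampleVerify()`) draws peptide pairs uniformly with
rejection sampling to the target class — the simplest defensible null,
reproducible bit-for-bit from the seed.  The shipped acceptance analysis
uses 1000 pairs per class plus a 100-pair BFS cross-check, which completes
in seconds; the uniform null does not emulate the residue composition of
real proteomes, database biases, or experimental label noise, so passing
verification demonstrates the mathematical property of the classifier, not
predictive accuracy on real peptides.

## Numerical choices and limitations

* Scores are computed in double precision; internal consistency assertions
  use $10^{-9}$, printed-value comparisons $5\times10^{-4}$.
* Degenerate inputs: a single-node path is valid with 0 edges; connecting a
  peptide to itself returns that trivial path; empty paths are errors.
* Input normalization: lowercase accepted, whitespace stripped; ambiguity
  codes (B, J, O, U, X, Z) are hard errors, never silently skipped.
* Predictive accuracy of the classifier itself (which requires the original
  experimentally labelled training data) is out of scope; the package takes
  the printed decision function as given and studies its structure.
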