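#' Position-weight amyloidogenicity effect matrix
#'
#' Holds the per-residue, per-position contributions of a linear peptide
#' classifier together with its intercept.  A peptide's amyloidogenicity
#' value is the sum of one contribution per position plus the intercept;
#' the peptide is predicted amyloidogenic when that value is non-negative.
#'
#' @slot contributions numeric matrix with one row per amino acid (rownames
#'   are the 20 canonical one-letter codes) and one column per peptide
#'   position.
#' @slot intercept single numeric, the additive constant of the decision
#'   function.
#'
#' @seealso [bapMatrix()] for the published hexapeptide matrix,
#'   [loadEffectMatrix()] to read one from TSV, [amyloidScore()].
#' @exportClass EffectMatrix
setClass("EffectMatrix",
         representation(contributions = "matrix", intercept = "numeric"))

setValidity("EffectMatrix", function(object) {
  m <- object@contributions
  if (!is.numeric(m) || ncol(m) < 1L)
    return("contributions must be a numeric matrix with at least one column")
  rn <- rownames(m)
  if (is.null(rn) || anyDuplicated(rn))
    return("contributions must have unique residue rownames")
  if (!setequal(rn, AA20) || nrow(m) != 20L) {
    missing <- setdiff(AA20, rn)
    extra <- setdiff(rn, AA20)
    return(sprintf("contribution rows must be exactly the 20 canonical residues (missing: %s; unexpected: %s)",
                   paste(missing, collapse = ","), paste(extra, collapse = ",")))
  }
  if (any(!is.finite(m)))
    return("all contribution values must be finite")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  TRUE
})

#' Per-position amyloidogenicity ordering of the residues
#'
#' For each peptide position, a total order of the 20 residues by
#' non-increasing contribution in an [EffectMatrix-class].  The first
#' residue of a row is the most amyloidogenic choice at that position.
#' Ties are broken deterministically by the recorded tie policy.
#'
#' @slot ranks character matrix, one row per position, 20 columns; row i
#'   lists the residues at position i from most to least amyloidogenic.
#' @slot contributions the numeric contribution matrix the ordering was
#'   derived from (residues x positions); retained so that the max/min
#'   operators can compare raw values, not just list ranks.
#' @slot tiePolicy single character string documenting how ties were broken.
#'
#' @seealso [deriveOrdering()], [maxResidue()], [minResidue()].
#' @exportClass PositionOrdering
setClass("PositionOrdering",
         representation(ranks = "matrix", contributions = "matrix",
                        tiePolicy = "character"))

setValidity("PositionOrdering", function(object) {
  r <- object@ranks
  if (!is.character(r) || ncol(r) != 20L)
    return("ranks must be a character matrix with 20 columns")
  bad <- which(apply(r, 1L, function(row) !setequal(row, AA20) || anyDuplicated(row)))
  if (length(bad))
    return(sprintf("ranks row(s) %s are not permutations of the 20 residues",
                   paste(bad, collapse = ",")))
  if (!identical(dim(object@contributions), c(20L, nrow(r))))
    return("contributions must be a 20 x length matrix matching ranks")
  v <- object@contributions
  for (i in seq_len(nrow(r))) {
    vals <- v[r[i, ], i]
    if (any(diff(vals) > 1e-12))
      return(sprintf("ranks row %d is not sorted by non-increasing contribution", i))
  }
  TRUE
})

#' A path in the hexapeptide mutation graph
#'
#' An ordered sequence of equal-length peptides in which consecutive
#' peptides differ in exactly one position (Hamming distance 1), i.e. a
#' walk along edges of the mutation graph.  The length of a path is its
#' number of edges, one less than its number of nodes.
#'
#' @slot nodes character vector of peptide sequences.
#'
#' @seealso [mutationPath()], [connectPeptides()], [validatePath()].
#' @exportClass MutationPath
setClass("MutationPath", representation(nodes = "character"))

setValidity("MutationPath", function(object) {
  p <- object@nodes
  if (length(p) < 1L)
    return("a path must contain at least one node")
  if (length(unique(nchar(p))) != 1L)
    return("all nodes must have equal length")
  chars <- strsplit(p, "", fixed = TRUE)
  bad <- which(vapply(chars, function(ch) any(!ch %in% AA20), logical(1L)))
  if (length(bad))
    return(sprintf("node(s) %s contain non-canonical residues",
                   paste(bad, collapse = ",")))
  if (length(p) > 1L) {
    d <- mapply(function(a, b) sum(a != b), chars[-length(chars)], chars[-1L])
    if (any(d != 1L))
      return(sprintf("consecutive nodes at step(s) %s do not differ in exactly one position",
                     paste(which(d != 1L), collapse = ",")))
  }
  TRUE
})

#' Result of connecting two same-class peptides
#'
#' The two-leg construction joins peptide pairs through their coordinate-wise
#' most (or least) amyloidogenic combination, the \emph{meet}: leg 1 runs
#' from the first peptide to the meet, leg 2 from the meet to the second
#' peptide, each changing one position at a time with monotone score.
#'
#' @slot path the full [MutationPath-class].
#' @slot meet the meet peptide; it sits at node index \code{leg1Length + 1}.
#' @slot leg1Length,leg2Length integer edge counts of the two legs.
#' @slot nodeScores numeric amyloidogenicity value of every node, in order.
#' @slot pathClass predicted class shared by all nodes.
#'
#' @seealso [connectPeptides()].
#' @exportClass PathReport
setClass("PathReport",
         representation(path = "MutationPath", meet = "character",
                        leg1Length = "integer", leg2Length = "integer",
                        nodeScores = "numeric", pathClass = "character"))

setValidity("PathReport", function(object) {
  n <- length(object@path@nodes)
  if (object@leg1Length + object@leg2Length != n - 1L)
    return("leg lengths must sum to the path edge count")
  if (!identical(object@path@nodes[object@leg1Length + 1L], object@meet))
    return("meet must appear at node index leg1Length + 1")
  if (length(object@nodeScores) != n)
    return("nodeScores must have one value per node")
  TRUE
})

#' Wildcard peptide pattern
#'
#' A template over peptide positions in which each slot is a non-empty set
#' of allowed residues: a singleton is a fixed residue, the full 20-residue
#' set is the wildcard \code{x}, and any other subset is a restricted
#' wildcard written \code{[...]}.  A pattern matches the Cartesian product
#' of its slots, e.g. \code{CxFLWx} matches \code{20^2 = 400} hexapeptides.
#'
#' @slot slots list of character vectors, one per position.
#'
#' @seealso [parsePattern()], [classifyPattern()], [patternExtremes()].
#' @exportClass Pattern
setClass("Pattern", representation(slots = "list"))

setValidity("Pattern", function(object) {
  s <- object@slots
  if (length(s) < 1L)
    return("a pattern needs at least one slot")
  for (i in seq_along(s)) {
    si <- s[[i]]
    if (!is.character(si) || length(si) < 1L)
      return(sprintf("slot %d must be a non-empty character vector", i))
    if (anyDuplicated(si) || any(!si %in% AA20))
      return(sprintf("slot %d must be a set of canonical residues", i))
  }
  TRUE
})

#' Outcome of checking a node sequence against the mutation graph and a class
#'
#' @slot isChain logical; \code{TRUE} when every consecutive pair of nodes is
#'   an edge of the mutation graph.
#' @slot homogeneousClass the class every node was checked against, or
#'   \code{NA_character_} when none was requested or inferable.
#' @slot nodeScores numeric score of every node.
#' @slot violations data.frame with columns \code{index} and \code{reason},
#'   one row per chain break or class violation (empty when the path is valid).
#'
#' @seealso [validatePath()].
#' @exportClass PathValidation
setClass("PathValidation",
         representation(isChain = "logical", homogeneousClass = "character",
                        nodeScores = "numeric", violations = "data.frame"))

#' Summary of a seeded verification run of the path construction
#'
#' @slot nPairs number of same-class peptide pairs connected.
#' @slot seed RNG seed used to draw them.
#' @slot maxPathLength largest edge count among the constructed paths.
#' @slot nClassViolations paths containing a node of the wrong class.
#' @slot nLengthViolations paths longer than the endpoint Hamming distance.
#'
#' @seealso [sampleVerify()].
#' @exportClass VerificationSummary
setClass("VerificationSummary",
         representation(nPairs = "integer", seed = "integer",
                        maxPathLength = "integer",
                        nClassViolations = "integer",
                        nLengthViolations = "integer"))

setValidity("VerificationSummary", function(object) {
  counts <- c(object@nClassViolations, object@nLengthViolations)
  if (any(counts < 0L) || any(counts > object@nPairs))
    return("violation counts must lie in [0, nPairs]")
  TRUE
})
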