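#' Coordinate-wise meet of two peptides
#'
#' For an amyloidogenic pair, the peptide whose residue at every position
#' is the more amyloidogenic of the two (the coordinate-wise maximum in the
#' per-position ordering); for a non-amyloidogenic pair, the coordinate-wise
#' minimum.  The meet dominates (or is dominated by) both inputs, so each
#' input connects to it by a score-monotone leg, which is what makes the
#' two-leg path construction work.
#'
#' @param o a [PositionOrdering-class].
#' @param p1,p2 peptides of the ordering's length.
#' @param cls `"amyloidogenic"` (meet = coordinate-wise max) or
#'   `"non_amyloidogenic"` (meet = coordinate-wise min).
#' @return a single peptide; each of its residues equals the corresponding
#'   residue of `p1` or `p2`.
#' @examples
#' o <- deriveOrdering(bapMatrix())
#' meetPeptide(o, "CVFFFF", "LYCLCI", "amyloidogenic")  # CYFLFI
#' @export
meetPeptide <- function(o, p1, p2, cls = c(CLASS_AMYLOID, CLASS_NONAMYLOID)) {
  cls <- match.arg(cls)
  k <- nrow(o@ranks)
  p1 <- checkPeptides(p1[1L], k); p2 <- checkPeptides(p2[1L], k)
  a <- strsplit(p1, "")[[1L]]; b <- strsplit(p2, "")[[1L]]
  op <- if (cls == CLASS_AMYLOID) maxResidue else minResidue
  paste(op(o, seq_len(k), a, b), collapse = "")
}

#' Score-monotone single-substitution leg between comparable peptides
#'
#' When `end` is coordinate-wise more (or less) amyloidogenic than `start`
#' at every position, substituting the differing positions one at a time —
#' in ascending position order — yields a path whose score is monotone
#' non-decreasing (resp. non-increasing).  The precondition is checked; a
#' non-comparable pair is an error, signalling that the caller must go
#' through the meet construction instead.
#'
#' @param m an [EffectMatrix-class].
#' @param o the matching [PositionOrdering-class].
#' @param start,end peptides.
#' @param direction `"non_decreasing"` (end dominates start) or
#'   `"non_increasing"` (start dominates end).
#' @return a [MutationPath-class] with `hammingDistance(start, end)` edges.
#' @examples
#' m <- bapMatrix(); o <- deriveOrdering(m)
#' pathNodes(monotoneLeg(m, o, "CVFFFF", "CYFLFI", "non_decreasing"))
#' @export
monotoneLeg <- function(m, o, start, end,
                        direction = c("non_decreasing", "non_increasing")) {
  direction <- match.arg(direction)
  k <- peptideLength(m)
  start <- checkPeptides(start[1L], k); end <- checkPeptides(end[1L], k)
  a <- strsplit(start, "")[[1L]]; b <- strsplit(end, "")[[1L]]
  ra <- .rankOf(o, seq_len(k), a); rb <- .rankOf(o, seq_len(k), b)
  ok <- if (direction == "non_decreasing") all(rb <= ra) else all(rb >= ra)
  if (!ok)
    stop("not coordinate-wise comparable: '", end, "' does not dominate '",
         start, "' in direction ", direction,
         "; connect through the meet peptide instead")
  nodes <- start
  cur <- a
  for (i in which(a != b)) {   # ascending position order
    cur[i] <- b[i]
    nodes <- c(nodes, paste(cur, collapse = ""))
  }
  mutationPath(nodes)
}

#' Connect two same-class peptides by a class-preserving path
#'
#' Builds a single-substitution path between two peptides of the same
#' predicted class such that every intermediate peptide keeps that class
#' and the total number of substitutions equals the Hamming distance of
#' the endpoints (hence at most the peptide length, and globally shortest
#' even among class-unconstrained paths).  Leg 1 climbs from `p1` to the
#' meet (coordinate-wise max for amyloidogenic pairs, min otherwise) with
#' monotone score; leg 2 descends from the meet to `p2`.  A position
#' changed in leg 1 is never changed again in leg 2.
#'
#' Mixed-class pairs are refused: the construction guarantees nothing for
#' paths between an amyloidogenic and a non-amyloidogenic peptide.
#'
#' @param m an [EffectMatrix-class].
#' @param o the matching [PositionOrdering-class]; derived from `m` when
#'   omitted.
#' @param p1,p2 peptides of the same predicted class.
#' @param leg2Order `"from-endpoint"`: build leg 2 from `p2` towards the
#'   meet in ascending position order, then reverse it (reproduces the
#'   published worked example); `"from-meet"`: substitute ascending
#'   positions starting at the meet (reproduces the published
#'   ILVWIW-to-FWLCYL path).  Either way every node keeps the class, since
#'   monotone legs are monotone under any substitution order.
#' @return a [PathReport-class].
#' @examples
#' m <- bapMatrix()
#' rep <- connectPeptides(m, p1 = "CVFFFF", p2 = "LYCLCI")
#' paste(pathNodes(rep@path), collapse = "-")
#' @export
connectPeptides <- function(m, o = deriveOrdering(m), p1, p2,
                            leg2Order = c("from-endpoint", "from-meet")) {
  leg2Order <- match.arg(leg2Order)
  k <- peptideLength(m)
  p1 <- checkPeptides(p1[1L], k); p2 <- checkPeptides(p2[1L], k)
  s1 <- unname(amyloidScore(m, p1)); s2 <- unname(amyloidScore(m, p2))
  c1 <- if (s1 >= 0) CLASS_AMYLOID else CLASS_NONAMYLOID
  c2 <- if (s2 >= 0) CLASS_AMYLOID else CLASS_NONAMYLOID
  if (c1 != c2)
    stop(sprintf(
      "cross-class pair: '%s' scores %.4f (%s) but '%s' scores %.4f (%s); %s",
      p1, s1, c1, p2, s2, c2,
      "nothing is claimed for paths between the two classes"))
  meet <- meetPeptide(o, p1, p2, c1)
  up <- if (c1 == CLASS_AMYLOID) "non_decreasing" else "non_increasing"
  down <- if (c1 == CLASS_AMYLOID) "non_increasing" else "non_decreasing"
  leg1 <- monotoneLeg(m, o, p1, meet, up)
  nodes1 <- pathNodes(leg1)
  nodes2 <- if (leg2Order == "from-endpoint") {
    rev(pathNodes(monotoneLeg(m, o, p2, meet, up)))
  } else {
    pathNodes(monotoneLeg(m, o, meet, p2, down))
  }
  nodes <- c(nodes1, nodes2[-1L])
  path <- mutationPath(nodes)
  new("PathReport", path = path, meet = meet,
      leg1Length = length(nodes1) - 1L,
      leg2Length = length(nodes2) - 1L,
      nodeScores = unname(amyloidScore(m, nodes)),
      pathClass = c1)
}

#' Shortest same-class path length by breadth-first search (oracle)
#'
#' Independent check of the two-leg construction: restricts the mutation
#' graph to a small sub-lattice (per position, a set of candidate residues
#' that must contain both endpoints' residues; by default the endpoints'
#' and the meet's residues, at most `3^length` nodes), drops every node
#' not of the endpoints' class, and finds the shortest path by
#' breadth-first search.  Because the default sub-lattice contains the
#' constructed two-leg path, a finite result bounded by the Hamming
#' distance certifies optimality of the construction.
#'
#' @param m an [EffectMatrix-class].
#' @param p1,p2 same-class peptides.
#' @param candidates optional list of per-position candidate residue sets.
#' @return integer shortest same-class path length within the sub-lattice,
#'   or `NA` if the endpoints are disconnected there.
#' @examples
#' bfsShortestClassPath(bapMatrix(), "CVFFFF", "LYCLCI")  # 6
#' @export
bfsShortestClassPath <- function(m, p1, p2, candidates = NULL) {
  k <- peptideLength(m)
  p1 <- checkPeptides(p1[1L], k); p2 <- checkPeptides(p2[1L], k)
  cls1 <- unname(predictClass(m, p1)); cls2 <- unname(predictClass(m, p2))
  if (cls1 != cls2)
    stop("cross-class pair: endpoints must share a predicted class")
  a <- strsplit(p1, "")[[1L]]; b <- strsplit(p2, "")[[1L]]
  if (is.null(candidates)) {
    meet <- meetPeptide(deriveOrdering(m), p1, p2, cls1)
    mres <- strsplit(meet, "")[[1L]]
    candidates <- lapply(seq_len(k), function(i) unique(c(a[i], b[i], mres[i])))
  } else {
    for (i in seq_len(k))
      if (!all(c(a[i], b[i]) %in% candidates[[i]]))
        stop("candidate set at position ", i,
             " must contain both endpoint residues")
  }
  grid <- do.call(expand.grid,
                  c(lapply(candidates, identity),
                    list(stringsAsFactors = FALSE)))
  nodes <- do.call(paste0, grid)
  nodes <- nodes[unname(predictClass(m, nodes)) == cls1]
  if (!all(c(p1, p2) %in% nodes))
    return(NA_integer_)   # cannot happen for same-class endpoints, defensive
  if (p1 == p2) return(0L)
  chars <- do.call(rbind, strsplit(nodes, "", fixed = TRUE))
  n <- length(nodes)
  pairs <- utils::combn(n, 2L)
  d <- rowSums(chars[pairs[1L, ], , drop = FALSE] !=
                 chars[pairs[2L, ], , drop = FALSE])
  edges <- pairs[, d == 1L, drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (ncol(edges))
    g <- igraph::add_edges(g, as.vector(edges))
  dist <- igraph::distances(g, v = match(p1, nodes), to = match(p2, nodes))
  if (!is.finite(dist[1L, 1L])) NA_integer_ else as.integer(dist[1L, 1L])
}

#' Verify the path construction on seeded random same-class pairs
#'
#' Draws peptides uniformly at random (rejection-sampling to the requested
#' class), forms `nPairs` pairs, connects each pair with
#' [connectPeptides()] and validates each constructed path with
#' [validatePath()].  Reports the maximal path length, the number of paths
#' containing a wrong-class node, and the number of paths longer than their
#' endpoints' Hamming distance.  Deterministic for a given seed.
#'
#' @param m an [EffectMatrix-class].
#' @param o the matching [PositionOrdering-class]; derived when omitted.
#' @param nPairs number of pairs to test.
#' @param seed RNG seed.
#' @param cls class to sample, `"amyloidogenic"` or `"non_amyloidogenic"`.
#' @return a [VerificationSummary-class].
#' @examples
#' sampleVerify(bapMatrix(), nPairs = 25, seed = 7, cls = "amyloidogenic")
#' @export
sampleVerify <- function(m, o = deriveOrdering(m), nPairs, seed,
                         cls = c(CLASS_AMYLOID, CLASS_NONAMYLOID)) {
  cls <- match.arg(cls)
  nPairs <- as.integer(nPairs)
  stopifnot(nPairs >= 0L)
  k <- peptideLength(m)
  set.seed(as.integer(seed))
  want <- 2L * nPairs
  kept <- character(0L)
  while (length(kept) < want) {
    batch <- max(200L, want)
    peps <- apply(matrix(sample(AA20, batch * k, replace = TRUE),
                         nrow = batch), 1L, paste, collapse = "")
    kept <- c(kept, peps[unname(predictClass(m, peps)) == cls])
  }
  kept <- kept[seq_len(want)]
  max_len <- 0L; n_class <- 0L; n_len <- 0L
  for (j in seq_len(nPairs)) {
    p1 <- kept[2L * j - 1L]; p2 <- kept[2L * j]
    rep <- connectPeptides(m, o, p1, p2)
    len <- pathLength(rep@path)
    max_len <- max(max_len, len)
    v <- validatePath(m, rep@path, cls)
    if (nrow(v@violations) && any(grepl("predicted", v@violations$reason)))
      n_class <- n_class + 1L
    if (len != hammingDistance(p1, p2, k))
      n_len <- n_len + 1L
  }
  new("VerificationSummary", nPairs = nPairs, seed = as.integer(seed),
      maxPathLength = as.integer(max_len),
      nClassViolations = n_class, nLengthViolations = n_len)
}
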