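#' Hamming distance between peptides
#'
#' Number of positions at which two equal-length peptides differ; the
#' mutation graph connects two peptides by an edge exactly when this
#' distance is 1, so the Hamming distance of two peptides is also the
#' smallest possible number of single-residue substitutions between them.
#'
#' @param p1,p2 peptide sequences (vectorized, recycled to a common length).
#' @param length peptide length both must have (default 6).
#' @return integer vector of distances.
#' @examples
#' hammingDistance("ILVWIW", "ALVWIW")  # 1
#' hammingDistance("ILVWIW", "IDDWIW")  # 2
#' @export
hammingDistance <- function(p1, p2, length = 6L) {
  n <- max(base::length(p1), base::length(p2))
  p1 <- checkPeptides(rep_len(p1, n), length)
  p2 <- checkPeptides(rep_len(p2, n), length)
  mapply(function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
         p1, p2, USE.NAMES = FALSE)
}

#' Are two peptides joined by an edge of the mutation graph?
#'
#' @inheritParams hammingDistance
#' @return logical vector: `TRUE` where the pair differs in exactly one
#'   position.
#' @examples
#' isEdge("ILVWIW", "ILVWID")  # TRUE
#' isEdge("HIKKLM", "VVKKLM")  # FALSE
#' @export
isEdge <- function(p1, p2, length = 6L) {
  hammingDistance(p1, p2, length) == 1L
}

#' All single-substitution neighbors of a peptide
#'
#' Enumerates every peptide at Hamming distance exactly 1: at each of the
#' positions, the original residue can be replaced by any of the other 19,
#' so a hexapeptide has 6 x 19 = 114 neighbors.  Order is deterministic:
#' position-major, then residue-alphabetical.
#'
#' @param p a single peptide.
#' @param length peptide length (default 6).
#' @return character vector of `19 * length` neighbors, excluding `p`.
#' @examples
#' length(neighborPeptides("ILVWIW"))  # 114
#' @export
neighborPeptides <- function(p, length = 6L) {
  p <- checkPeptides(p[1L], length)
  res <- strsplit(p, "", fixed = TRUE)[[1L]]
  aa_sorted <- sort(AA20)
  out <- character(0L)
  for (i in seq_len(length)) {
    for (r in setdiff(aa_sorted, res[i])) {
      q <- res; q[i] <- r
      out <- c(out, paste(q, collapse = ""))
    }
  }
  out
}

#' Construct a mutation path from node sequences
#'
#' @param nodes character vector of peptides; consecutive entries must
#'   differ in exactly one position (validated).
#' @return a [MutationPath-class].
#' @examples
#' mutationPath(c("CVFFFF", "CYFFFF", "CYFLFF"))
#' @export
mutationPath <- function(nodes) {
  new("MutationPath", nodes = toupper(as.character(nodes)))
}

#' @describeIn MutationPath-class the node sequence.
#' @export
setMethod("pathNodes", "MutationPath", function(x, ...) x@nodes)

#' @describeIn MutationPath-class the path length, i.e. its number of edges
#'   (one less than its node count).
#' @export
setMethod("pathLength", "MutationPath",
          function(x, ...) length(x@nodes) - 1L)

#' @describeIn MutationPath-class coerce to the node character vector.
#' @param x a `MutationPath`.
#' @param ... ignored.
#' @export
setMethod("as.character", "MutationPath", function(x, ...) x@nodes)

#' Check a node sequence as a class-homogeneous mutation-graph path
#'
#' Verifies the chain property (every consecutive pair an edge), scores
#' every node, and — when a class is given or inferable from the first
#' node — records every node predicted to the other class.  Unlike
#' [mutationPath()], this accepts arbitrary node sequences so that broken
#' chains can be diagnosed rather than rejected.
#'
#' @param m an [EffectMatrix-class].
#' @param path a [MutationPath-class] or character vector of peptides.
#' @param expectedClass `"amyloidogenic"`, `"non_amyloidogenic"`, or `NULL`
#'   to infer the class from the first node.
#' @return a [PathValidation-class].
#' @examples
#' m <- bapMatrix()
#' v <- validatePath(m, c("ILVWIW", "IWVWIW", "IWVCIW"))
#' v@isChain
#' @export
validatePath <- function(m, path, expectedClass = NULL) {
  nodes <- if (is(path, "MutationPath")) path@nodes else as.character(path)
  if (!length(nodes))
    stop("empty path")
  nodes <- checkPeptides(nodes, peptideLength(m))
  scores <- unname(amyloidScore(m, nodes))
  cls <- if (is.null(expectedClass)) {
    if (scores[1L] >= 0) CLASS_AMYLOID else CLASS_NONAMYLOID
  } else match.arg(expectedClass, c(CLASS_AMYLOID, CLASS_NONAMYLOID))
  viol <- data.frame(index = integer(0L), reason = character(0L))
  is_chain <- TRUE
  if (length(nodes) > 1L) {
    d <- hammingDistance(nodes[-length(nodes)], nodes[-1L], peptideLength(m))
    for (i in which(d != 1L)) {
      is_chain <- FALSE
      viol <- rbind(viol, data.frame(
        index = i + 1L,
        reason = sprintf("Hamming distance %d to previous node (edge requires 1)",
                         d[i])))
    }
  }
  node_cls <- ifelse(scores >= 0, CLASS_AMYLOID, CLASS_NONAMYLOID)
  for (i in which(node_cls != cls)) {
    viol <- rbind(viol, data.frame(
      index = i,
      reason = sprintf("node predicted %s, expected %s (A = %.4f)",
                       node_cls[i], cls, scores[i])))
  }
  new("PathValidation", isChain = is_chain, homogeneousClass = cls,
      nodeScores = scores, violations = viol)
}

#' Read / write path files
#'
#' Two plain-text layouts are supported: one peptide per line, or a single
#' line of peptides joined by dashes (`CVFFFF-CYFFFF-...`), the notation
#' used for printed example paths.  `writePathFile` picks the layout via
#' `format`.
#'
#' @param file path to a text file.
#' @return `readPathFile`: a [MutationPath-class].
#' @export
readPathFile <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 1L && grepl("-", lines, fixed = TRUE))
    lines <- strsplit(lines, "-", fixed = TRUE)[[1L]]
  mutationPath(trimws(lines))
}

#' @rdname readPathFile
#' @param path a [MutationPath-class] or character vector of nodes.
#' @param format `"dash"` for the single-line dashed notation, `"list"` for
#'   one peptide per line.
#' @return `writePathFile`: `file`, invisibly.
#' @export
writePathFile <- function(path, file, format = c("dash", "list")) {
  format <- match.arg(format)
  nodes <- if (is(path, "MutationPath")) path@nodes else as.character(path)
  writeLines(switch(format,
                    dash = paste(nodes, collapse = "-"),
                    list = nodes),
             file)
  invisible(file)
}
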