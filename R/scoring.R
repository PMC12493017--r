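#' Validate and normalize peptide sequences
#'
#' Uppercases, strips whitespace, and checks that every residue is one of
#' the 20 canonical one-letter codes and that the length matches.
#' Ambiguity codes (B, J, O, U, X, Z) are a hard error, not skipped.
#'
#' @param peptides character vector of peptide sequences.
#' @param length required peptide length (default 6).
#' @return the normalized character vector, invisibly valid.
#' @export
checkPeptides <- function(peptides, length = 6L) {
  p <- toupper(gsub("[[:space:]]", "", as.character(peptides)))
  if (any(is.na(p)))
    stop("NA peptide sequence")
  badlen <- which(nchar(p) != length)
  if (length(badlen))
    stop(sprintf("peptide %d ('%s') has length %d, expected %d",
                 badlen[1L], p[badlen[1L]], nchar(p[badlen[1L]]), length))
  chars <- strsplit(p, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!chars[[i]] %in% AA20)
    if (length(bad))
      stop(sprintf("peptide %d ('%s'): invalid residue '%s' at position %d",
                   i, p[i], chars[[i]][bad[1L]], bad[1L]))
  }
  p
}

# residue matrix (n x length) from validated peptides, no checks
.pepMatrix <- function(peptides) {
  do.call(rbind, strsplit(peptides, "", fixed = TRUE))
}

#' Amyloidogenicity value of peptides
#'
#' Computes the decision value A(x) = intercept + sum over positions i of
#' the contribution of residue x\[i\] at position i.  Peptides with
#' A(x) >= 0 are predicted amyloidogenic.
#'
#' @param m an [EffectMatrix-class].
#' @param peptides character vector of peptides of length
#'   `peptideLength(m)`; lowercase accepted, whitespace stripped.
#' @return numeric vector of scores, named by peptide.
#' @examples
#' m <- bapMatrix()
#' amyloidScore(m, c("YVSTSY", "ILVWIW"))
#' @export
amyloidScore <- function(m, peptides) {
  k <- peptideLength(m)
  p <- checkPeptides(peptides, k)
  if (!length(p)) return(stats::setNames(numeric(0L), character(0L)))
  pm <- .pepMatrix(p)
  terms <- matrix(m@contributions[cbind(as.vector(pm),
                                        rep(seq_len(k), each = length(p)))],
                  nrow = length(p))
  stats::setNames(rowSums(terms) + m@intercept, p)
}

#' Predicted amyloidogenicity class of peptides
#'
#' Applies the sign rule of the linear classifier: a score that is positive
#' or exactly zero means amyloidogenic, a negative score non-amyloidogenic.
#'
#' @inheritParams amyloidScore
#' @return character vector, `"amyloidogenic"` or `"non_amyloidogenic"`,
#'   named by peptide.
#' @examples
#' predictClass(bapMatrix(), "YVSTSY")  # non_amyloidogenic
#' @export
predictClass <- function(m, peptides) {
  s <- amyloidScore(m, peptides)
  stats::setNames(ifelse(s >= 0, CLASS_AMYLOID, CLASS_NONAMYLOID), names(s))
}

#' Per-position decomposition of a peptide's score
#'
#' @param m an [EffectMatrix-class].
#' @param peptide a single peptide sequence.
#' @return a list with elements `contributions` (numeric per-position terms,
#'   named residue+position), `intercept`, and `total`
#'   (their sum, equal to [amyloidScore()]).
#' @examples
#' scoreBreakdown(bapMatrix(), "YVSTSY")
#' @export
scoreBreakdown <- function(m, peptide) {
  k <- peptideLength(m)
  p <- checkPeptides(peptide[1L], k)
  res <- strsplit(p, "", fixed = TRUE)[[1L]]
  terms <- m@contributions[cbind(res, seq_len(k))]
  names(terms) <- paste0(res, seq_len(k))
  list(contributions = terms, intercept = m@intercept,
       total = sum(terms) + m@intercept)
}
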