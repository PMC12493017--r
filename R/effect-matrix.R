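#' Construct an effect matrix
#'
#' @param contributions numeric matrix, 20 residue rows (rownames are the
#'   one-letter codes) by one column per peptide position.
#' @param intercept single numeric additive constant of the decision value.
#' @return an [EffectMatrix-class].
#' @examples
#' m <- bapMatrix()
#' peptideLength(m)
#' contribution(m, "V", 6)
#' @export
effectMatrix <- function(contributions, intercept) {
  contributions <- as.matrix(contributions)
  storage.mode(contributions) <- "double"
  colnames(contributions) <- as.character(seq_len(ncol(contributions)))
  new("EffectMatrix", contributions = contributions[AA20, , drop = FALSE],
      intercept = as.numeric(intercept))
}

#' The published hexapeptide amyloid effect matrix
#'
#' Returns the embedded 20x6 amyloid effect matrix with intercept 1.083,
#' the decision function of the published hexapeptide amyloidogenicity
#' classifier, exactly as printed (contributions to two decimals).
#'
#' @return an [EffectMatrix-class] of length 6.
#' @examples
#' amyloidScore(bapMatrix(), "YVSTSY")  # -0.557
#' @export
bapMatrix <- function() {
  new("EffectMatrix", contributions = .BAP_CONTRIBUTIONS,
      intercept = .BAP_INTERCEPT)
}

#' @describeIn EffectMatrix-class the residue-by-position contribution matrix.
#' @export
setMethod("contributions", "EffectMatrix", function(x, ...) x@contributions)

#' @describeIn EffectMatrix-class the intercept of the decision value.
#' @export
setMethod("intercept", "EffectMatrix", function(x, ...) x@intercept)

#' @describeIn EffectMatrix-class the peptide length the matrix scores
#'   (number of columns).
#' @export
setMethod("peptideLength", "EffectMatrix",
          function(x, ...) ncol(x@contributions))

#' Look up a single contribution value
#'
#' @param m an [EffectMatrix-class].
#' @param residue one-letter code.
#' @param position position index in 1..peptideLength(m).
#' @return numeric contribution of `residue` at `position`.
#' @examples
#' contribution(bapMatrix(), "A", 1)  # -0.26
#' @export
contribution <- function(m, residue, position) {
  residue <- toupper(residue)
  if (any(!residue %in% AA20))
    stop("unknown residue code: ", paste(setdiff(residue, AA20), collapse = ","))
  position <- as.integer(position)
  if (any(position < 1L) || any(position > peptideLength(m)))
    stop("position out of range 1..", peptideLength(m))
  m@contributions[cbind(residue, position)]
}

#' Read an effect matrix from a TSV file
#'
#' The expected layout is a header line `res<TAB>1<TAB>...<TAB>L`, twenty
#' data rows (one per residue), and the intercept either as a final data
#' row labelled `__intercept__` (value in the first position column) or
#' supplied through the `intercept` argument.  With `file = NULL` the
#' embedded published matrix is returned.
#'
#' @param file path to a TSV file, or `NULL` for the embedded matrix.
#' @param intercept optional numeric overriding / replacing the
#'   `__intercept__` row.
#' @return an [EffectMatrix-class].
#' @seealso [writeEffectMatrix()] for the inverse.
#' @export
loadEffectMatrix <- function(file = NULL, intercept = NULL) {
  if (is.null(file)) {
    m <- bapMatrix()
    if (!is.null(intercept)) m@intercept <- as.numeric(intercept)
    return(m)
  }
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("matrix file must have a residue column plus position columns")
  res <- tab[[1L]]
  icept_row <- res == "__intercept__"
  if (any(icept_row)) {
    if (is.null(intercept)) intercept <- as.numeric(tab[icept_row, 2L][1L])
    tab <- tab[!icept_row, , drop = FALSE]
    res <- tab[[1L]]
  }
  if (is.null(intercept))
    stop("no intercept: supply one or include an '__intercept__' row")
  dup <- res[duplicated(res)]
  if (length(dup))
    stop("duplicate residue row(s): ", paste(unique(dup), collapse = ","))
  missing <- setdiff(AA20, res)
  if (length(missing))
    stop("missing residue row(s): ", paste(missing, collapse = ","))
  extra <- setdiff(res, AA20)
  if (length(extra))
    stop("unknown residue row(s): ", paste(extra, collapse = ","))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(res, colnames(vals))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at residue %s, position column %s",
                 res[bad[1L]], colnames(vals)[bad[2L]]))
  }
  effectMatrix(num, intercept)
}

#' Write an effect matrix to TSV
#'
#' Writes the layout read back by [loadEffectMatrix()]: a header, twenty
#' residue rows and a final `__intercept__` row.
#'
#' @param m an [EffectMatrix-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeEffectMatrix <- function(m, file) {
  k <- peptideLength(m)
  lines <- c(paste(c("res", seq_len(k)), collapse = "\t"),
             vapply(AA20, function(r) {
               paste(c(r, format(m@contributions[r, ], trim = TRUE)),
                     collapse = "\t")
             }, character(1L)),
             paste(c("__intercept__", format(m@intercept, trim = TRUE),
                     rep("", k - 1L)), collapse = "\t"))
  writeLines(lines, file)
  invisible(file)
}
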