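#' Read peptides from a list or FASTA file
#'
#' List files carry one peptide per line; blank lines and `#` comments are
#' ignored.  FASTA files are read with \pkg{Biostrings}; sequence lines of
#' each record are concatenated and record identifiers are kept as names.
#' `format = "auto"` treats a leading `>` as FASTA.  Every record is
#' validated against the required length.
#'
#' @param file input path.
#' @param format `"auto"`, `"list"` or `"fasta"`.
#' @param length required peptide length (default 6).
#' @return named character vector of validated peptides.
#' @export
readPeptides <- function(file, format = c("auto", "list", "fasta"),
                         length = 6L) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L)
    format <- if (base::length(first) && startsWith(trimws(first), ">"))
      "fasta" else "list"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(file)
    peps <- stats::setNames(as.character(seqs), names(seqs))
  } else {
    lines <- trimws(readLines(file))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    peps <- stats::setNames(lines, lines)
  }
  for (i in seq_along(peps)) {
    ok <- try(checkPeptides(peps[[i]], length), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("record '", names(peps)[i], "': ",
           conditionMessage(attr(ok, "condition")))
    peps[[i]] <- ok
  }
  peps
}

#' Write a score report as TSV
#'
#' Columns: peptide, score, class.
#'
#' @param m an [EffectMatrix-class].
#' @param peptides character vector of peptides (names, if any, are kept
#'   as an extra leading `id` column).
#' @param file output path.
#' @return the report data.frame, invisibly.
#' @export
writeScoreReport <- function(m, peptides, file) {
  s <- amyloidScore(m, unname(peptides))
  df <- data.frame(peptide = names(s), score = unname(s),
                   class = ifelse(s >= 0, CLASS_AMYLOID, CLASS_NONAMYLOID))
  if (!is.null(names(peptides)))
    df <- cbind(id = names(peptides), df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Seeded synthetic fixtures: random peptides and (optionally) a random matrix
#'
#' Draws `nPeptides` peptides uniformly over the 20-residue alphabet.  With
#' `randomMatrix = TRUE`, also draws an effect matrix with contributions
#' uniform on \[-0.6, 0.3\] (the span of the published matrix) and sets the
#' intercept to minus the median raw score of a seeded 1000-peptide sample,
#' which guarantees both predicted classes are non-empty.  Such matrices
#' exercise the construction's generality: the class-preserving path
#' property holds for any linear position-weight classifier, not just the
#' published one.
#'
#' @param seed RNG seed; the result is bit-for-bit reproducible.
#' @param nPeptides number of peptides to draw.
#' @param randomMatrix draw a random matrix instead of the published one?
#' @param length peptide length (default 6).
#' @return list with elements `matrix` ([EffectMatrix-class]) and
#'   `peptides` (character vector).
#' @examples
#' fx <- makeFixtures(seed = 1, nPeptides = 5, randomMatrix = TRUE)
#' table(predictClass(fx$matrix, fx$peptides))
#' @export
makeFixtures <- function(seed, nPeptides, randomMatrix = FALSE, length = 6L) {
  stopifnot(nPeptides >= 0L)
  set.seed(as.integer(seed))
  m <- if (randomMatrix) {
    contrib <- matrix(stats::runif(20L * length, -0.6, 0.3),
                      nrow = 20L, dimnames = list(AA20, NULL))
    m0 <- effectMatrix(contrib, 0)
    probe <- apply(matrix(sample(AA20, 1000L * length, replace = TRUE),
                          nrow = 1000L), 1L, paste, collapse = "")
    effectMatrix(contrib, -stats::median(unname(amyloidScore(m0, probe))))
  } else {
    bapMatrix()
  }
  peps <- if (nPeptides > 0L) {
    apply(matrix(sample(AA20, nPeptides * length, replace = TRUE),
                 nrow = nPeptides), 1L, paste, collapse = "")
  } else character(0L)
  list(matrix = m, peptides = peps)
}
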