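#' The published per-position amyloidogenicity ordering, as printed
#'
#' Returns the published reference table of per-position residue orderings
#' (most amyloidogenic first), one 20-character string per position,
#' verbatim.  Kept for auditing only: row 4 is internally inconsistent as
#' printed (C occurs twice, V is absent), which [compareToReference()]
#' reports and never repairs.
#'
#' @return character vector of 6 strings of 20 residue letters.
#' @export
bapPrintedOrdering <- function() .BAP_PRINTED_ORDER

#' Derive per-position residue orderings from an effect matrix
#'
#' Sorts, for each position, the 20 residues by decreasing contribution.
#' Ties are broken by the corresponding row of `reference` where that row
#' is a valid permutation of the 20 residues, and alphabetically otherwise,
#' so the result is deterministic and reproduces the published table
#' wherever the published row is self-consistent.
#'
#' @param m an [EffectMatrix-class].
#' @param reference optional character vector of per-position residue
#'   orderings used only for tie-breaking; defaults to the published table
#'   when `m` has length 6, else none (alphabetical ties).
#' @return a [PositionOrdering-class].
#' @examples
#' o <- deriveOrdering(bapMatrix())
#' rankTable(o)[1, 1:5]  # V I C L F
#' @export
deriveOrdering <- function(m, reference = NULL) {
  k <- peptideLength(m)
  if (is.null(reference) && k == length(.BAP_PRINTED_ORDER))
    reference <- .BAP_PRINTED_ORDER
  ranks <- matrix("", nrow = k, ncol = 20L,
                  dimnames = list(as.character(seq_len(k)), NULL))
  policy <- character(k)
  for (i in seq_len(k)) {
    ref_row <- if (!is.null(reference) && i <= length(reference))
      strsplit(reference[i], "", fixed = TRUE)[[1L]] else character(0L)
    if (length(ref_row) == 20L && setequal(ref_row, AA20)) {
      tiekey <- match(AA20, ref_row)
      policy[i] <- "reference"
    } else {
      tiekey <- match(AA20, sort(AA20))
      policy[i] <- "alphabetical"
    }
    ranks[i, ] <- AA20[order(-m@contributions[AA20, i], tiekey)]
  }
  new("PositionOrdering", ranks = ranks,
      contributions = m@contributions[AA20, , drop = FALSE],
      tiePolicy = paste0("ties by ",
                         paste(unique(policy), collapse = "/"),
                         " order"))
}

#' @describeIn deriveOrdering the per-position rank table: a character
#'   matrix with one row per position, residues left to right from most to
#'   least amyloidogenic.
#' @param o a [PositionOrdering-class].
#' @export
rankTable <- function(o) o@ranks

.rankOf <- function(o, pos, residues) {
  pos <- as.integer(pos)
  if (any(pos < 1L) || any(pos > nrow(o@ranks)))
    stop("position out of range 1..", nrow(o@ranks))
  residues <- toupper(residues)
  bad <- setdiff(residues, AA20)
  if (length(bad))
    stop("unknown residue code: ", paste(bad, collapse = ","))
  idx <- t(o@ranks[pos, , drop = FALSE])
  vapply(seq_along(residues),
         function(j) match(residues[j], idx[, j]), integer(1L))
}

#' Most / least amyloidogenic of two residues at a position
#'
#' `maxResidue` returns whichever of the two residues ranks earlier (more
#' amyloidogenic) in the ordering row of the given position — the leftmost
#' in the published table; `minResidue` the rightmost.  With equal
#' residues the common residue is returned.  All arguments are vectorized.
#'
#' @param o a [PositionOrdering-class].
#' @param pos position index (1-based), recycled against the residues.
#' @param r1,r2 one-letter residue codes.
#' @return character vector of residues.
#' @examples
#' o <- deriveOrdering(bapMatrix())
#' maxResidue(o, 3, "Y", "I")  # I
#' minResidue(o, 4, "E", "S")  # S
#' @export
maxResidue <- function(o, pos, r1, r2) {
  n <- max(length(pos), length(r1), length(r2))
  pos <- rep_len(as.integer(pos), n)
  r1 <- rep_len(toupper(r1), n); r2 <- rep_len(toupper(r2), n)
  ifelse(.rankOf(o, pos, r1) <= .rankOf(o, pos, r2), r1, r2)
}

#' @rdname maxResidue
#' @export
minResidue <- function(o, pos, r1, r2) {
  n <- max(length(pos), length(r1), length(r2))
  pos <- rep_len(as.integer(pos), n)
  r1 <- rep_len(toupper(r1), n); r2 <- rep_len(toupper(r2), n)
  ifelse(.rankOf(o, pos, r1) >= .rankOf(o, pos, r2), r1, r2)
}

#' Audit a derived ordering against a printed reference table
#'
#' Compares each position's derived residue order with a reference row
#' (rank by rank) and additionally reports residues that the reference row
#' lists more than once or not at all.  Reference rows need not be
#' permutations: the audit tolerates typos and reports them rather than
#' failing, so the published table can be checked as printed.
#'
#' @param o a [PositionOrdering-class].
#' @param reference character vector of length-20 residue strings, one per
#'   position; defaults to the published printed table.
#' @return a list with data.frames `mismatches` (position, rank, derived,
#'   reference, and `tied` — whether the two residues have equal
#'   contribution, i.e. the mismatch is a tie-order artifact),
#'   `duplicates` and `missing` (position, residue) describing defects of
#'   the reference rows themselves.
#' @examples
#' audit <- compareToReference(deriveOrdering(bapMatrix()))
#' audit$duplicates  # position 4 lists C twice
#' @export
compareToReference <- function(o, reference = bapPrintedOrdering()) {
  k <- nrow(o@ranks)
  mism <- list(); dups <- list(); miss <- list()
  for (i in seq_len(min(k, length(reference)))) {
    ref <- strsplit(reference[i], "", fixed = TRUE)[[1L]]
    der <- o@ranks[i, ]
    ncmp <- min(length(ref), length(der))
    diff_at <- which(der[seq_len(ncmp)] != ref[seq_len(ncmp)])
    if (length(diff_at)) {
      tied <- vapply(diff_at, function(r) {
        rr <- toupper(ref[r])
        rr %in% AA20 &&
          abs(o@contributions[der[r], i] - o@contributions[rr, i]) < 1e-12
      }, logical(1L))
      mism[[length(mism) + 1L]] <-
        data.frame(position = i, rank = diff_at, derived = der[diff_at],
                   reference = ref[diff_at], tied = tied)
    }
    d <- unique(ref[duplicated(ref)])
    if (length(d))
      dups[[length(dups) + 1L]] <- data.frame(position = i, residue = d)
    ms <- setdiff(AA20, ref)
    if (length(ms))
      miss[[length(miss) + 1L]] <- data.frame(position = i, residue = ms)
  }
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(character(0L)),
                                            length(cols)), cols))
    df
  }
  list(
    mismatches = if (length(mism)) do.call(rbind, mism)
                 else empty(c("position", "rank", "derived", "reference", "tied")),
    duplicates = if (length(dups)) do.call(rbind, dups)
                 else empty(c("position", "residue")),
    missing = if (length(miss)) do.call(rbind, miss)
              else empty(c("position", "residue"))
  )
}
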