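#' Parse a wildcard peptide pattern
#'
#' Grammar, one token per position: an upper-case one-letter residue code
#' fixes the position; `x` (or `X`) allows all 20 residues; a bracketed
#' group such as `[ILV]` allows exactly the listed residues (a restricted
#' wildcard).  `"CxFLWx"` therefore matches 400 hexapeptides.
#'
#' @param text pattern string.
#' @param length required number of positions (default 6).
#' @return a [Pattern-class].
#' @examples
#' patternCardinality(parsePattern("CxFLWx"))   # 400
#' patternSlots(parsePattern("Cx[ILV]LWx"))[[3]]
#' @export
parsePattern <- function(text, length = 6L) {
  text <- gsub("[[:space:]]", "", as.character(text)[1L])
  slots <- list()
  i <- 1L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  while (i <= base::length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(close))
        stop("unterminated '[' at character ", i, " of pattern '", text, "'")
      if (close == i + 1L)
        stop("empty residue set '[]' in pattern '", text, "'")
      grp <- toupper(chars[(i + 1L):(close - 1L)])
      bad <- setdiff(grp, AA20)
      if (base::length(bad))
        stop("invalid residue '", bad[1L], "' in bracketed set of pattern '",
             text, "'")
      slots[[base::length(slots) + 1L]] <- sort(unique(grp))
      i <- close + 1L
    } else if (ch %in% c("x", "X")) {
      slots[[base::length(slots) + 1L]] <- sort(AA20)
      i <- i + 1L
    } else if (toupper(ch) %in% AA20) {
      slots[[base::length(slots) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop("invalid pattern character '", ch, "' in '", text, "'")
    }
  }
  if (base::length(slots) != length)
    stop("pattern '", text, "' has ", base::length(slots),
         " positions, expected ", length)
  new("Pattern", slots = slots)
}

#' @describeIn Pattern-class the per-position allowed-residue sets.
#' @export
setMethod("patternSlots", "Pattern", function(x, ...) x@slots)

#' @describeIn Pattern-class number of peptides the pattern matches
#'   (product of slot sizes).
#' @export
setMethod("patternCardinality", "Pattern",
          function(x, ...) prod(vapply(x@slots, length, integer(1L))))

#' Format a pattern back to its string notation
#'
#' @param pat a [Pattern-class].
#' @return the pattern string; full 20-residue slots print as `x`,
#'   other multi-residue slots as `[...]`.
#' @export
formatPattern <- function(pat) {
  paste(vapply(pat@slots, function(s) {
    if (length(s) == 20L) "x"
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' Exact score extrema over all peptides matching a pattern
#'
#' Because the score is a sum of independent per-position terms, the
#' minimum (maximum) over all matching peptides is attained by choosing,
#' in each slot, a residue of minimal (maximal) contribution — a closed
#' form, no enumeration.  Residue ties within a slot break alphabetically.
#'
#' Extrema within 0.03 of the decision threshold are flagged as
#' rounding-sensitive: with a matrix printed to two decimals such margins
#' are inside the accumulated rounding error of six terms, so the true
#' (unrounded) classifier could fall on the other side.
#'
#' @param m an [EffectMatrix-class].
#' @param pat a [Pattern-class] (or pattern string).
#' @return list with `min`, `max` (scores), `argmin`, `argmax` (peptides
#'   attaining them), and `roundingSensitive` (logical).
#' @examples
#' patternExtremes(bapMatrix(), "CxFLWx")  # min 0.063 at CKFLWP
#' @export
patternExtremes <- function(m, pat) {
  if (is.character(pat)) pat <- parsePattern(pat, peptideLength(m))
  k <- peptideLength(m)
  if (length(pat@slots) != k)
    stop("pattern has ", length(pat@slots), " positions, matrix expects ", k)
  lo <- hi <- numeric(k)
  amin <- amax <- character(k)
  for (i in seq_len(k)) {
    s <- sort(pat@slots[[i]])  # alphabetical tie-break via which.min/max
    v <- m@contributions[s, i]
    lo[i] <- min(v); hi[i] <- max(v)
    amin[i] <- s[which.min(v)]; amax[i] <- s[which.max(v)]
  }
  out <- list(min = sum(lo) + m@intercept, max = sum(hi) + m@intercept,
              argmin = paste(amin, collapse = ""),
              argmax = paste(amax, collapse = ""))
  out$roundingSensitive <- min(abs(out$min), abs(out$max)) < 0.03
  out
}

#' Classify a pattern by the sign of its score extrema
#'
#' A pattern is all-amyloidogenic when even its worst-scoring match is
#' non-negative, all-non-amyloidogenic when even its best-scoring match is
#' strictly negative, and mixed otherwise.  Threshold-consistent with
#' [predictClass()] (score 0 counts as amyloidogenic).
#'
#' @inheritParams patternExtremes
#' @return one of `"all_amyloidogenic"`, `"all_non_amyloidogenic"`,
#'   `"mixed"`.
#' @examples
#' classifyPattern(bapMatrix(), "xxIVIV")  # all_amyloidogenic
#' classifyPattern(bapMatrix(), "PxDxxx")  # all_non_amyloidogenic
#' @export
classifyPattern <- function(m, pat) {
  ex <- patternExtremes(m, pat)
  if (ex$min >= 0) "all_amyloidogenic"
  else if (ex$max < 0) "all_non_amyloidogenic"
  else "mixed"
}

#' Enumerate the peptides matching a pattern
#'
#' @inheritParams patternExtremes
#' @param cap refuse patterns matching more than this many peptides.
#' @return character vector of all matching peptides.
#' @export
enumeratePattern <- function(m, pat, cap = 1e7) {
  if (is.character(pat)) pat <- parsePattern(pat, peptideLength(m))
  card <- patternCardinality(pat)
  if (card > cap)
    stop("pattern matches ", format(card, big.mark = ","),
         " peptides, over the enumeration cap (", format(cap, big.mark = ","),
         "); use patternExtremes() for closed-form bounds instead")
  grid <- do.call(expand.grid, c(rev(pat@slots),
                                 list(stringsAsFactors = FALSE)))
  do.call(paste0, rev(grid))
}

#' Count matching peptides of a given predicted class
#'
#' Full enumeration of the pattern's matches, scored and filtered to the
#' requested class.  Refused above the enumeration cap — use
#' [patternExtremes()] there, whose sign bounds are exact.
#'
#' @inheritParams enumeratePattern
#' @param cls `"amyloidogenic"` or `"non_amyloidogenic"`.
#' @return integer count.
#' @examples
#' countClass(bapMatrix(), "CxFLWx", "amyloidogenic")  # 400
#' @export
countClass <- function(m, pat, cls = c(CLASS_AMYLOID, CLASS_NONAMYLOID),
                       cap = 1e7) {
  cls <- match.arg(cls)
  peps <- enumeratePattern(m, pat, cap)
  sum(unname(predictClass(m, peps)) == cls)
}
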