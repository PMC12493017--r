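setMethod("show", "EffectMatrix", function(object) {
  cat(sprintf("EffectMatrix: 20 residues x %d positions, intercept %.3f\n",
              peptideLength(object), object@intercept))
  print(round(object@contributions, 3))
})

setMethod("show", "PositionOrdering", function(object) {
  cat(sprintf("PositionOrdering: %d positions (%s)\n",
              nrow(object@ranks), object@tiePolicy))
  for (i in seq_len(nrow(object@ranks)))
    cat(sprintf("  %d: %s\n", i, paste(object@ranks[i, ], collapse = " ")))
})

setMethod("show", "MutationPath", function(object) {
  cat(sprintf("MutationPath: %d nodes, %d edges\n  %s\n",
              length(object@nodes), length(object@nodes) - 1L,
              paste(object@nodes, collapse = "-")))
})

setMethod("show", "PathReport", function(object) {
  cat(sprintf("PathReport (%s): %d edges, meet %s (legs %d + %d)\n",
              object@pathClass, pathLength(object@path), object@meet,
              object@leg1Length, object@leg2Length))
  cat(sprintf("  %s\n", paste(pathNodes(object@path), collapse = "-")))
  cat("  scores:", paste(sprintf("%.3f", object@nodeScores), collapse = " "),
      "\n")
})

setMethod("show", "Pattern", function(object) {
  cat(sprintf("Pattern %s matching %s peptide(s)\n", formatPattern(object),
              format(patternCardinality(object), big.mark = ",")))
})

setMethod("show", "PathValidation", function(object) {
  cat(sprintf("PathValidation: chain %s, class %s, %d node(s), %d violation(s)\n",
              ifelse(object@isChain, "ok", "BROKEN"),
              object@homogeneousClass, length(object@nodeScores),
              nrow(object@violations)))
  if (nrow(object@violations)) print(object@violations)
})

setMethod("show", "VerificationSummary", function(object) {
  cat(sprintf(paste0("VerificationSummary: %d pairs (seed %d), ",
                     "max path length %d, %d class / %d length violations\n"),
              object@nPairs, object@seed, object@maxPathLength,
              object@nClassViolations, object@nLengthViolations))
})
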