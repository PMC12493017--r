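# Shared fixtures: the published matrix and its derived ordering.
BAP <- bapMatrix()
ORD <- deriveOrdering(BAP)

# Seeded random peptides, as plain strings.
randomPeptides <- function(n, seed, length = 6L) {
  set.seed(seed)
  apply(matrix(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                      n * length, replace = TRUE), nrow = n),
        1L, paste, collapse = "")
}

# Brute-force score: per-position table lookup written independently of
# amyloidScore() (direct subscripting, explicit loop).
bruteScore <- function(m, pep) {
  ch <- strsplit(pep, "")[[1]]
  total <- intercept(m)
  for (i in seq_along(ch)) total <- total + contributions(m)[ch[i], i]
  total
}
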