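# The 20 proteinogenic amino acids, one-letter codes, in the conventional
# A/R/N/D/... order used by the effect matrix rows.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity / non-canonical one-letter codes that are rejected outright.
AA_REJECT <- c("B", "J", "O", "U", "X", "Z")

CLASS_AMYLOID <- "amyloidogenic"
CLASS_NONAMYLOID <- "non_amyloidogenic"

# Amyloid effect matrix: per-residue, per-position contributions to the
# linear decision value of the hexapeptide classifier.  Rows are residues,
# columns are hexapeptide positions 1..6.  Values are exact as published
# (two decimals); the intercept below completes the decision function.
.BAP_CONTRIBUTIONS <- matrix(c(
  # pos:   1,     2,     3,     4,     5,     6
  -0.26, -0.32, -0.27, -0.14, -0.43, -0.22,  # A
  -0.45, -0.41, -0.46, -0.33, -0.52, -0.35,  # R
  -0.40, -0.34, -0.49, -0.27, -0.46, -0.30,  # N
  -0.49, -0.43, -0.56, -0.41, -0.56, -0.36,  # D
  -0.09, -0.21,  0.03, -0.05, -0.17, -0.05,  # C
  -0.37, -0.30, -0.36, -0.34, -0.48, -0.32,  # Q
  -0.51, -0.41, -0.43, -0.30, -0.61, -0.39,  # E
  -0.23, -0.37, -0.46, -0.37, -0.30, -0.33,  # G
  -0.32, -0.26, -0.26, -0.30, -0.35, -0.25,  # H
  -0.06, -0.08,  0.26,  0.09, -0.06, -0.07,  # I
  -0.10, -0.18,  0.02,  0.04, -0.22, -0.13,  # L
  -0.39, -0.45, -0.51, -0.35, -0.59, -0.32,  # K
  -0.17, -0.25, -0.02, -0.10, -0.19, -0.18,  # M
  -0.13, -0.11,  0.05, -0.03, -0.13, -0.11,  # F
  -0.56, -0.38, -0.56, -0.51, -0.42, -0.45,  # P
  -0.37, -0.35, -0.41, -0.30, -0.48, -0.23,  # S
  -0.34, -0.33, -0.28, -0.23, -0.40, -0.23,  # T
  -0.17, -0.17, -0.09, -0.06, -0.12, -0.16,  # W
  -0.23, -0.11, -0.13, -0.06, -0.18, -0.15,  # Y
  -0.05, -0.14,  0.19,  0.14, -0.19,  0.01   # V
), nrow = 20L, ncol = 6L, byrow = TRUE,
   dimnames = list(AA20, as.character(1:6)))

.BAP_INTERCEPT <- 1.083

# Published per-position amyloidogenicity orderings (most amyloidogenic
# first), kept verbatim as an audit reference.  Row 4 is internally
# inconsistent as printed (C appears twice, V is absent); the audit reports
# this, it is never repaired.
.BAP_PRINTED_ORDER <- c(
  "VICLFMWGYAHTSQKNRDEP",
  "IFYVWLCMHQATNSGPREDK",
  "IVFCLMWYHATQSERGNKDP",
  "CILFCWYMATNHESRQKGDP",
  "IWFCYMVLGHTPANQSRDKE",
  "VCIFLYWMATSHNQKGRDEP"
)
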