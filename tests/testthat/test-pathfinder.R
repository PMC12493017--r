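test_that("the meet is the coordinate-wise extreme of the pair", {
  expect_equal(meetPeptide(ORD, "CVFFFF", "LYCLCI", "amyloidogenic"), "CYFLFI")
  expect_equal(meetPeptide(ORD, "ILVWIW", "FWLCYL", "amyloidogenic"), "IWVCIL")
  expect_equal(meetPeptide(ORD, "YVSTSY", "YVSTSY", "amyloidogenic"), "YVSTSY")
  expect_equal(meetPeptide(ORD, "YVSTSY", "YVSTSY", "non_amyloidogenic"),
               "YVSTSY")
  # every coordinate comes from one of the two inputs
  set.seed(61)
  for (rep in 1:50) {
    pq <- randomPeptides(2, seed = 600 + rep)
    for (cls in c("amyloidogenic", "non_amyloidogenic")) {
      mt <- strsplit(meetPeptide(ORD, pq[1], pq[2], cls), "")[[1]]
      a <- strsplit(pq[1], "")[[1]]; b <- strsplit(pq[2], "")[[1]]
      expect_true(all(mt == a | mt == b))
    }
  }
})

test_that("monotone legs reproduce the worked example and refuse incomparable pairs", {
  leg1 <- monotoneLeg(BAP, ORD, "CVFFFF", "CYFLFI", "non_decreasing")
  expect_equal(pathNodes(leg1), c("CVFFFF", "CYFFFF", "CYFLFF", "CYFLFI"))
  leg2 <- monotoneLeg(BAP, ORD, "LYCLCI", "CYFLFI", "non_decreasing")
  expect_equal(pathNodes(leg2), c("LYCLCI", "CYCLCI", "CYFLCI", "CYFLFI"))
  expect_equal(pathNodes(monotoneLeg(BAP, ORD, "CVFFFF", "CVFFFF",
                                     "non_decreasing")),
               "CVFFFF")
  # CVFFFF and LYCLCI dominate each other in neither direction
  expect_error(monotoneLeg(BAP, ORD, "CVFFFF", "LYCLCI", "non_decreasing"),
               "not coordinate-wise comparable")
})

test_that("connecting two amyloidogenic peptides reproduces the printed path byte-for-byte", {
  rep <- connectPeptides(BAP, ORD, "CVFFFF", "LYCLCI")
  expect_equal(pathNodes(rep@path),
               c("CVFFFF", "CYFFFF", "CYFLFF", "CYFLFI",
                 "CYFLCI", "CYCLCI", "LYCLCI"))
  expect_equal(rep@meet, "CYFLFI")
  expect_equal(pathLength(rep@path), 6L)
  expect_equal(rep@leg1Length + rep@leg2Length, 6L)
  expect_equal(pathNodes(rep@path)[rep@leg1Length + 1L], rep@meet)
  expect_equal(rep@pathClass, "amyloidogenic")
  expect_true(all(rep@nodeScores >= 0))
})

test_that("the alternative leg-2 order reproduces the other printed path", {
  rep <- connectPeptides(BAP, ORD, "ILVWIW", "FWLCYL", leg2Order = "from-meet")
  expect_equal(pathNodes(rep@path),
               c("ILVWIW", "IWVWIW", "IWVCIW", "IWVCIL",
                 "FWVCIL", "FWLCIL", "FWLCYL"))
  expect_equal(rep@meet, "IWVCIL")
  # both orders preserve class and total length
  rep2 <- connectPeptides(BAP, ORD, "ILVWIW", "FWLCYL",
                          leg2Order = "from-endpoint")
  expect_equal(pathLength(rep2@path), 6L)
  expect_true(all(rep2@nodeScores >= 0))
})

test_that("degenerate and cross-class requests behave as specified", {
  rep <- connectPeptides(BAP, ORD, "YVSTSY", "YVSTSY")
  expect_equal(pathNodes(rep@path), "YVSTSY")
  expect_equal(pathLength(rep@path), 0L)
  err <- expect_error(connectPeptides(BAP, ORD, "YVSTSY", "ILVWIW"),
                      "cross-class")
  expect_match(conditionMessage(err), "-0.557")
})

test_that("path length always equals the endpoint Hamming distance and scores are monotone per leg", {
  set.seed(71)
  for (rep_i in 1:100) {
    pair <- randomPeptides(2, seed = 7000 + rep_i)
    cls <- unname(predictClass(BAP, pair))
    if (cls[1] != cls[2]) next
    rep <- connectPeptides(BAP, ORD, pair[1], pair[2])
    expect_equal(pathLength(rep@path), hammingDistance(pair[1], pair[2]))
    expect_lte(pathLength(rep@path), 6L)
    s <- rep@nodeScores
    i_meet <- rep@leg1Length + 1L
    sgn <- if (cls[1] == "amyloidogenic") 1 else -1
    expect_true(all(diff(sgn * s[seq_len(i_meet)]) >= -1e-12))
    expect_true(all(diff(sgn * s[i_meet:length(s)]) <= 1e-12))
    # meet dominance
    expect_gte(sgn * s[i_meet],
               max(sgn * s[1], sgn * s[length(s)]) - 1e-12)
    # leg complementarity: a position changed in leg 1 never changes in leg 2
    nodes <- pathNodes(rep@path)
    chpos <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    changed1 <- unique(unlist(mapply(chpos, nodes[seq_len(i_meet - 1)],
                                     nodes[2:i_meet], SIMPLIFY = FALSE)))
    if (i_meet < length(nodes)) {
      changed2 <- unique(unlist(mapply(chpos,
                                       nodes[i_meet:(length(nodes) - 1)],
                                       nodes[(i_meet + 1):length(nodes)],
                                       SIMPLIFY = FALSE)))
      expect_length(intersect(changed1, changed2), 0L)
    }
    # no wrong-class node anywhere
    v <- validatePath(BAP, rep@path, cls[1])
    expect_equal(nrow(v@violations), 0L)
  }
})

test_that("the BFS oracle agrees with the construction on sampled same-class pairs", {
  expect_equal(bfsShortestClassPath(BAP, "CVFFFF", "LYCLCI"), 6L)
  expect_equal(bfsShortestClassPath(BAP, "ILVWIW", "ALVWIW"), 1L)
  expect_equal(bfsShortestClassPath(BAP, "YVSTSY", "YVSTSY"), 0L)
  expect_error(bfsShortestClassPath(BAP, "YVSTSY", "ILVWIW"), "cross-class")
  set.seed(81)
  tested <- 0L
  rep_i <- 0L
  while (tested < 20L) {
    rep_i <- rep_i + 1L
    pair <- randomPeptides(2, seed = 8000 + rep_i)
    cls <- unname(predictClass(BAP, pair))
    if (cls[1] != cls[2]) next
    tested <- tested + 1L
    expect_equal(bfsShortestClassPath(BAP, pair[1], pair[2]),
                 pathLength(connectPeptides(BAP, ORD, pair[1], pair[2])@path))
  }
})

test_that("seeded verification finds no violations and is reproducible", {
  v <- sampleVerify(BAP, ORD, nPairs = 100, seed = 42, cls = "amyloidogenic")
  expect_equal(v@nPairs, 100L)
  expect_lte(v@maxPathLength, 6L)
  expect_equal(v@nClassViolations, 0L)
  expect_equal(v@nLengthViolations, 0L)
  v2 <- sampleVerify(BAP, ORD, nPairs = 100, seed = 42, cls = "amyloidogenic")
  expect_equal(v, v2)
  vn <- sampleVerify(BAP, ORD, nPairs = 100, seed = 42,
                     cls = "non_amyloidogenic")
  expect_lte(vn@maxPathLength, 6L)
  expect_equal(vn@nClassViolations + vn@nLengthViolations, 0L)
  v0 <- sampleVerify(BAP, ORD, nPairs = 0, seed = 1, cls = "amyloidogenic")
  expect_equal(v0@maxPathLength, 0L)
  expect_equal(v0@nPairs, 0L)
})

test_that("the construction holds for arbitrary random linear classifiers", {
  for (seed in 1:20) {
    fx <- makeFixtures(seed = seed, nPeptides = 0, randomMatrix = TRUE)
    m <- fx$matrix
    o <- deriveOrdering(m)
    set.seed(seed + 900)
    for (cls in c("amyloidogenic", "non_amyloidogenic")) {
      got <- 0L; tries <- 0L
      while (got < 3L && tries < 200L) {
        tries <- tries + 1L
        pair <- randomPeptides(2, seed = seed * 1000 + tries)
        pcls <- unname(predictClass(m, pair))
        if (pcls[1] != cls || pcls[2] != cls) next
        got <- got + 1L
        rep <- connectPeptides(m, o, pair[1], pair[2])
        expect_equal(pathLength(rep@path), hammingDistance(pair[1], pair[2]))
        expect_equal(nrow(validatePath(m, rep@path, cls)@violations), 0L)
        sgn <- if (cls == "amyloidogenic") 1 else -1
        i_meet <- rep@leg1Length + 1L
        expect_gte(sgn * rep@nodeScores[i_meet],
                   sgn * rep@nodeScores[1] - 1e-12)
        expect_gte(sgn * rep@nodeScores[i_meet],
                   sgn * rep@nodeScores[length(rep@nodeScores)] - 1e-12)
      }
      expect_gte(got, 1L)  # random intercept centering leaves both classes non-empty
    }
  }
})
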