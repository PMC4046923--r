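base <- blosum62()

test_that("per-pair matrix selection follows the region rule", {
  p <- heptadProtein()
  set <- buildMatrixSet(p, p, alignParams("ccalignx"))
  # both non-cc
  expect_equal(selectMatrix(FALSE, FALSE, "-", "-", 0.1, 0.1, set)$tag,
               "NONCC")
  # mixed
  expect_equal(selectMatrix(TRUE, FALSE, "a", "-", 0.9, 0.1, set)$tag,
               "MIXED")
  # both cc, ccalignx: the more confident prediction's register wins
  sel <- selectMatrix(TRUE, TRUE, "a", "e", 0.95, 0.90, set,
                      mode = "ccalignx")
  expect_equal(sel$tag, "AD")
  expect_false(sel$bonusApplies)
  # matched register d -> AD with bonus
  sel2 <- selectMatrix(TRUE, TRUE, "d", "d", 0.9, 0.9, set,
                       mode = "ccalignx")
  expect_equal(sel2$tag, "AD")
  expect_true(sel2$bonusApplies)
  # ccalign mode: always the generic cc matrix, never a bonus
  sel3 <- selectMatrix(TRUE, TRUE, "d", "d", 0.9, 0.9, set,
                       mode = "ccalign")
  expect_equal(sel3$tag, "CC")
  expect_false(sel3$bonusApplies)
})

test_that("plain alignment equals the exhaustive brute-force oracle", {
  mat <- scores(base)
  params <- alignParams("plain", gapOpen = 10L)
  set.seed(99)
  for (i in 1:12) {
    a <- randomProtein("a", sample(3:5, 1))
    b <- randomProtein("b", sample(3:5, 1))
    got <- ccAlign(a, b, params)@rawScore
    want <- bruteLocalScore(as.character(a), as.character(b), mat,
                            10L, 1L)
    expect_equal(got, want)
  }
})

test_that("plain alignment equals an independent reference aligner", {
  # Biostrings implements local Smith-Waterman-Gotoh with the same
  # first-gap convention; 300 random pairs on the full alphabet
  data(BLOSUM62, package = "Biostrings", envir = environment())
  params <- alignParams("plain")
  set.seed(7)
  for (i in 1:300) {
    a <- randomProtein("a", sample(4:12, 1),
                       alphabet = strsplit("ARNDCQEGHILKMFPSTWYV",
                                           "")[[1]])
    b <- randomProtein("b", sample(4:12, 1),
                       alphabet = strsplit("ARNDCQEGHILKMFPSTWYV",
                                           "")[[1]])
    got <- ccAlign(a, b, params)@rawScore
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(as.character(a)),
      Biostrings::AAString(as.character(b)), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(got, as.integer(ref))
  }
})

test_that("unalignable inputs give the empty alignment", {
  a <- CCProtein("a", "XXXX")
  b <- CCProtein("b", "XXXX")
  al <- ccAlign(a, b, alignParams("plain"))
  expect_equal(al@rawScore, 0L)
  expect_equal(nrow(al@pairs), 0L)
  expect_equal(al@qStart, 0L)
})

test_that("raw score is invariant to appended runs of X", {
  params <- alignParams("ccalign")
  p <- heptadProtein("p1")
  q <- heptadProtein("p2", nHept = 4L)
  s0 <- ccAlign(p, q, params)@rawScore
  pX <- CCProtein("p1x", paste0(as.character(p), strrep("X", 15)),
                  ccProb = c(ccProb(p), rep(0, 15)),
                  register = c(register(p), rep("-", 15)))
  expect_equal(ccAlign(pX, q, params)@rawScore, s0)
})

test_that("the register bonus adds exactly beta per matched pair", {
  p <- heptadProtein("p1", nHept = 4L)
  q <- heptadProtein("p2", nHept = 4L)
  a0 <- ccAlign(p, q, alignParams("ccalignx", bonus = 0))
  a3 <- ccAlign(p, q, alignParams("ccalignx", bonus = 3))
  expect_gt(a3@nBonus, 0L)
  expect_equal(a3@rawScore - a0@rawScore, 3L * a3@nBonus)
})

test_that("alignment score is symmetric under the max-confidence rule", {
  sim <- simulateFamilies(familySpec(nFamilies = 3L, seed = 5L))
  params <- alignParams("ccalign", confidenceRule = "max")
  for (f in 1:3) {
    A <- sim$proteomes$sp1[[f]]
    B <- sim$proteomes$sp2[[f]]
    expect_equal(ccAlign(A, B, params)@rawScore,
                 ccAlign(B, A, params)@rawScore)
  }
})

test_that("without any annotation ccalign reduces to one full matrix", {
  sim <- simulateFamilies(familySpec(nFamilies = 2L, seed = 9L))
  A0 <- CCProtein("a", as.character(sim$proteomes$sp1[[1]]))
  B0 <- CCProtein("b", as.character(sim$proteomes$sp2[[1]]))
  params <- alignParams("ccalign")
  al <- ccAlign(A0, B0, params)
  # every aligned pair is scored by the non-cc matrix, which equals the
  # full-length matrix when nothing is coiled-coil
  set <- buildMatrixSet(A0, B0, params)
  expect_identical(scores(set@mNonCC), scores(set@mFull))
  expect_true(all(al@pairs$tag[al@pairs$tag != ""] == "NONCC"))
})

test_that("alignment raw score is recomputable from the traceback", {
  sim <- simulateFamilies(familySpec(nFamilies = 2L, seed = 21L))
  A <- sim$proteomes$sp1[[1]]; B <- sim$proteomes$sp2[[2]]
  for (mode in c("plain", "ccalign", "ccalignx")) {
    params <- alignParams(mode)
    set <- buildMatrixSet(A, B, params)
    al <- ccAlign(A, B, params, set = set)
    bank <- CoilAlign:::bankFromSet(set, params)
    slotOf <- c(MIXED = 1L, NONCC = 2L, CC = 3L, AD = 0L, EG = 0L,
                BCF = 0L)
    charsA <- strsplit(as.character(A), "")[[1]]
    charsB <- strsplit(as.character(B), "")[[1]]
    effA <- effectiveRegister(A, partitionProtein(A, params@ccCutoff))
    effB <- effectiveRegister(B, partitionProtein(B, params@ccCutoff))
    total <- 0L
    prevGap <- 0L  # 0 none, 1 gap in subject, 2 gap in query
    for (r in seq_len(nrow(al@pairs))) {
      qp <- al@pairs$qpos[r]; sp <- al@pairs$spos[r]
      if (qp > 0 && sp > 0) {
        tag <- al@pairs$tag[r]
        k <- if (tag %in% c("AD", "EG", "BCF", "CC") &&
                 mode != "plain") {
          # register slot of the winning register
          regW <- if (ccProb(A)[qp] >= ccProb(B)[sp]) effA[qp] else
            effB[sp]
          if (regW == "-") 3L else 3L + match(regW, letters[1:7])
        } else slotOf[[tag]]
        if (mode == "plain") k <- 1L
        total <- total + bank[[k]][charsA[qp], charsB[sp]]
        if (al@pairs$bonus[r]) total <- total + as.integer(params@bonus)
        prevGap <- 0L
      } else {
        gapType <- if (sp == 0) 1L else 2L
        total <- total - (if (prevGap == gapType) params@gapExtend else
          params@gapOpen + params@gapExtend)
        prevGap <- gapType
      }
    }
    expect_equal(total, al@rawScore)
    expect_gte(al@rawScore, 0L)
  }
})

test_that("bit scores follow the Karlin-Altschul form", {
  expect_equal(round(bitScore(0, 0.267, 0.041), 2), 4.61)
  expect_equal(round(bitScore(50, 0.267, 0.041), 2), 23.87)
  expect_true(all(diff(bitScore(0:100)) > 0))  # monotone
  expect_error(bitScore(1, lambda = 0), "lambda")
})

test_that("batch search equals the single-pair path in every mode", {
  sim <- simulateFamilies(familySpec(nFamilies = 3L, seed = 13L))
  q <- sim$proteomes$sp1
  s <- sim$proteomes$sp2[1:6]
  for (mode in c("plain", "ccalign", "ccalignx")) {
    params <- alignParams(mode)
    raw <- CoilAlign:::bestHitScores(q, s, params)
    for (i in seq_along(q)) for (j in seq_along(s))
      expect_equal(unname(raw[i, j]),
                   ccAlign(q[[i]], s[[j]], params)@rawScore)
  }
})
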