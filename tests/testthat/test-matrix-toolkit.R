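base <- blosum62()

test_that("composition blends counts with background pseudocounts", {
  bgU <- rep(0.05, 20)
  # empty sequence returns the background unchanged
  expect_equal(unname(computeComposition("", 20, bgU)$freq), bgU)
  # no pseudocounts: degenerate frequencies are produced as-is
  c0 <- computeComposition("AAAA", 0, bgU)
  expect_equal(unname(c0$freq[1]), 1)
  expect_equal(sum(c0$freq == 0), 19L)
  # hand arithmetic: "ACDE", mass 20, uniform background
  c1 <- computeComposition("ACDE", 20, bgU)
  expect_equal(unname(c1$freq["A"]), 2 / 24)
  expect_equal(sum(c1$freq), 1)
  expect_equal(c1$nObs, 4L)
  # X is not counted
  expect_equal(computeComposition("ACDEXX", 20, bgU)$nObs, 4L)
})

test_that("relative entropy matches hand computations and brute force", {
  # independence -> 0
  p <- rep(0.05, 20)
  expect_equal(matrixRelativeEntropy(outer(p, p), p, p), 0)
  # 2-letter toy: 0.4 log2 1.6 * 2 + 0.1 log2 0.4 * 2 = 0.278 bits
  q2 <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  h2 <- matrixRelativeEntropy(q2, c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(h2, 0.8 * log2(1.6) + 0.2 * log2(0.4))
  expect_equal(round(h2, 3), 0.278)
  # brute-force double loop agreement to 1e-12
  q <- jointQ(base)
  brute <- 0
  for (a in 1:20) for (b in 1:20)
    if (q[a, b] > 0)
      brute <- brute + q[a, b] *
        log2(q[a, b] / (base@bgRow[a] * base@bgCol[b]))
  expect_equal(relEntropyBits(base), unname(brute), tolerance = 1e-12)
  # zero cells contribute nothing (limit convention)
  qz <- q; qz[1, 2] <- 0; qz <- qz / sum(qz)
  expect_true(is.finite(matrixRelativeEntropy(qz, rowSums(qz),
                                              colSums(qz))))
})

test_that("adjustment with the base background is a no-op", {
  m <- adjustMatrix(base, base@bgRow, base@bgCol)
  expect_identical(scores(m), scores(base))
  expect_identical(jointQ(m), jointQ(base))
})

test_that("adjusted matrices satisfy marginal and entropy constraints", {
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(30:300, 1); n2 <- sample(30:300, 1)
    c1 <- (stats::rmultinom(1, n1, base@bgRow *
                              exp(stats::rnorm(20, 0, 0.7)))[, 1] +
             20 * base@bgRow) / (n1 + 20)
    c2 <- (stats::rmultinom(1, n2, base@bgRow *
                              exp(stats::rnorm(20, 0, 0.7)))[, 1] +
             20 * base@bgRow) / (n2 + 20)
    m <- adjustMatrix(base, c1, c2)
    expect_false(m@fallback)
    q <- jointQ(m)
    expect_lt(max(abs(rowSums(q) - c1)), 1e-6)
    expect_lt(max(abs(colSums(q) - c2)), 1e-6)
    expect_lt(abs(relEntropyBits(m) - relEntropyBits(base)), 1e-6)
    # valid log-odds matrix: expected score positive under q,
    # negative under the independent background
    sc <- scores(m)[1:20, 1:20]
    expect_gt(sum(q * sc), 0)
    expect_lt(sum(outer(c1, c2) * sc), 0)
    # idempotence in distribution
    m2 <- adjustMatrix(m, c1, c2)
    expect_lt(max(abs(jointQ(m2) - q)), 1e-6)
  }
})

test_that("coiled-coil adjustment raises proline scores", {
  # hydrophilic-rich coiled-coil compositions deplete proline; the
  # log-odds for the rare letter rises relative to the full-length
  # adjustment
  ccSeq <- strrep("LIEKLASLQEKLASLIERLAE", 4)
  fullSeq <- paste0(ccSeq, strrep("PGPSTPNDPGPMWC", 8))
  cCC1 <- computeComposition(ccSeq)
  cFull1 <- computeComposition(fullSeq)
  mCC <- adjustMatrix(base, cCC1, cCC1)
  mFull <- adjustMatrix(base, cFull1, cFull1)
  expect_gt(scores(mCC)["P", "P"], scores(mFull)["P", "P"])
})

test_that("register weights follow the chosen scheme", {
  H <- c(AD = 0.45, EG = 0.32, BCF = 0.28)
  wMed <- computeRegisterWeights(H, "median")
  expect_equal(unname(wMed), c(0.45, 0.32, 0.28) / 0.32,
               tolerance = 1e-12)
  expect_equal(round(unname(wMed), 3), c(1.406, 1.000, 0.875))
  wB <- computeRegisterWeights(H, "blosum", hBase = 0.70)
  expect_equal(round(unname(wB), 3), c(0.643, 0.457, 0.400))
  # equal entropies -> unit weights
  expect_equal(unname(computeRegisterWeights(
    c(AD = 0.4, EG = 0.4, BCF = 0.4), "median")), rep(1, 3))
  expect_equal(unname(computeRegisterWeights(H, "off")), rep(1, 3))
  expect_error(computeRegisterWeights(c(AD = 0.4, EG = 0.3), "median"),
               "missing")
})

test_that("NCBI matrix text and sidecar round-trip", {
  tmp <- tempfile(fileext = ".mat")
  writeScoreMatrix(base, tmp, sidecar = TRUE)
  m <- readScoreMatrix(tmp)
  expect_identical(scores(m), scores(base))
  expect_equal(jointQ(m), jointQ(base), tolerance = 1e-10)
  expect_equal(relEntropyBits(m), relEntropyBits(base),
               tolerance = 1e-9)
  # without sidecar the probabilities are reconstructed from scores
  tmp2 <- tempfile(fileext = ".mat")
  writeScoreMatrix(base, tmp2)
  m2 <- readScoreMatrix(tmp2)
  expect_identical(scores(m2), scores(base))
  expect_lt(max(abs(rowSums(jointQ(m2)) - base@bgRow)), 1e-6)
})
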