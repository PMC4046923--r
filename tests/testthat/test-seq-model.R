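test_that("partitioning thresholds at >= cutoff and reconstructs runs", {
  # below cutoff everywhere -> one non-cc interval
  p <- CCProtein("p", strrep("A", 10), ccProb = 0.5)
  part <- partitionProtein(p, 0.8)
  expect_length(ccIntervals(part), 0)
  expect_equal(as.data.frame(nonccIntervals(part))[, c("start", "end")],
               data.frame(start = 1L, end = 10L))

  # boundary: exactly 0.8 is coiled-coil
  p2 <- CCProtein("p2", strrep("A", 5), ccProb = c(0, 0, 0.8, 0, 0))
  part2 <- partitionProtein(p2, 0.8)
  expect_equal(IRanges::start(ccIntervals(part2)), 3L)
  expect_equal(IRanges::end(ccIntervals(part2)), 3L)

  # mask 000111110011100 -> cc [4,8],[11,13]; non-cc [1,3],[9,10],[14,15]
  mask <- as.integer(strsplit("000111110011100", "")[[1]])
  p3 <- CCProtein("p3", strrep("L", 15), ccProb = mask * 0.9)
  part3 <- partitionProtein(p3, 0.8)
  expect_equal(IRanges::start(ccIntervals(part3)), c(4L, 11L))
  expect_equal(IRanges::end(ccIntervals(part3)), c(8L, 13L))
  expect_equal(IRanges::start(nonccIntervals(part3)), c(1L, 9L, 14L))
  expect_equal(IRanges::end(nonccIntervals(part3)), c(3L, 10L, 15L))
})

test_that("empty or invalid proteins are rejected", {
  expect_error(CCProtein("p", ""), "empty")
  expect_error(CCProtein("p", "AB1"), "invalid")
  expect_error(CCProtein("p", "ACD", ccProb = c(0, 1)), "equal length")
  expect_error(partitionProtein(CCProtein("p", "ACD"), 0), "cutoff")
})

test_that("subsequence extraction splits registers into groups", {
  # heptad abcdefg repeated twice, all coiled-coil
  p <- CCProtein("p", "LIEKLASLIEKLAS", ccProb = 0.95,
                 register = rep(letters[1:7], 2))
  sub <- extractSubsequences(p, partitionProtein(p))
  expect_equal(nchar(sub$AD), 4L)
  expect_equal(nchar(sub$EG), 4L)
  expect_equal(nchar(sub$BCF), 6L)
  expect_equal(sub$cc, as.character(p))
  expect_equal(sub$noncc, "")
  expect_equal(nchar(sub$cc), nchar(sub$AD) + nchar(sub$EG) +
                 nchar(sub$BCF))

  # no coiled-coil -> everything empty except noncc
  p2 <- CCProtein("p2", "ACDEFGH")
  sub2 <- extractSubsequences(p2, partitionProtein(p2))
  expect_equal(sub2$cc, "")
  expect_equal(sub2$AD, "")
  expect_equal(sub2$noncc, "ACDEFGH")
})

test_that("register gaps inside coiled-coil runs inherit neighbours", {
  reg <- c("-", "a", "b", "-", "d", "-", "-")
  p <- CCProtein("p", "LLLLLLL", ccProb = c(0, rep(0.9, 6)),
                 register = reg)
  eff <- effectiveRegister(p, partitionProtein(p))
  expect_equal(eff[1], "-")           # non-cc stays unassigned
  expect_equal(eff[4], "b")           # tie between b (left) and d -> left
  expect_equal(eff[6], "d")
  expect_equal(eff[7], "d")
  # a cc run with no registers at all stays unassigned but remains cc
  p2 <- CCProtein("p2", "LLLL", ccProb = 0.9)
  expect_warning(sub <- extractSubsequences(p2, partitionProtein(p2)),
                 "no register")
  expect_equal(sub$cc, "LLLL")
  expect_equal(sub$AD, "")
})

test_that("interval round-trips reproduce the input", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    prob <- stats::runif(n)
    p <- CCProtein("p", paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                              "")[[1]], n, TRUE),
                              collapse = ""), ccProb = prob)
    part <- partitionProtein(p, 0.6)
    mask <- prob >= 0.6
    # intervals -> mask -> intervals is the identity
    expect_equal(CoilAlign:::intervalsToMask(ccIntervals(part), n), mask)
    rebuilt <- CoilAlign:::maskToIntervals(mask)
    expect_equal(as.data.frame(rebuilt), as.data.frame(ccIntervals(part)))
    # concatenating region subsequences in coordinate order reproduces p
    sub <- suppressWarnings(extractSubsequences(p, part))
    chars <- strsplit(as.character(p), "")[[1]]
    expect_equal(paste0(sub$cc, sub$noncc), paste(
      c(chars[mask], chars[!mask]), collapse = ""))
  }
})

test_that("sequence hygiene on construction", {
  expect_warning(p <- CCProtein("p", "acU*de"), "mapped to X")
  expect_equal(as.character(p), "ACXDE")
  expect_equal(length(p), 5L)
})

test_that("cc content and the 20% coiled-coil protein rule", {
  p <- CCProtein("p", strrep("A", 150),
                 ccProb = c(rep(0.9, 30), rep(0, 120)))
  expect_equal(ccContent(p), 0.2)
  expect_true(ccContent(p) >= 0.20)  # classified coiled-coil protein
  expect_equal(ccContent(CCProtein("q", "AAAA", ccProb = 0.95)), 1)
  expect_equal(ccContent(CCProtein("r", "AAAA")), 0)
})
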