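test_that("the generator is reproducible and validates its spec", {
  s1 <- simulateFamilies(familySpec(nFamilies = 5L, seed = 17L))
  s2 <- simulateFamilies(familySpec(nFamilies = 5L, seed = 17L))
  expect_identical(lapply(s1$proteomes$sp1, as.character),
                   lapply(s2$proteomes$sp1, as.character))
  expect_identical(lapply(s1$proteomes$sp2, as.character),
                   lapply(s2$proteomes$sp2, as.character))
  expect_identical(s1$gold, s2$gold)
  # a different seed changes the sequences
  s3 <- simulateFamilies(familySpec(nFamilies = 5L, seed = 18L))
  expect_false(identical(as.character(s1$proteomes$sp1[[1]]),
                         as.character(s3$proteomes$sp1[[1]])))
  expect_error(familySpec(divergence = 1.2), "divergence")
  expect_error(familySpec(domainLength = c(3L, 10L)), "at least 7")
})

test_that("zero divergence gives identical descendants", {
  s <- simulateFamilies(familySpec(nFamilies = 4L, divergence = 0,
                                   seed = 2L))
  for (f in 1:4)
    expect_equal(as.character(s$proteomes$sp1[[f]]),
                 as.character(s$proteomes$sp2[[f]]))
})

test_that("interface positions are hydrophobic at the designed rate", {
  s <- simulateFamilies(familySpec(nFamilies = 40L, seed = 23L))
  hyd <- strsplit("LIVMAF", "")[[1]]
  n <- 0L; k <- 0L
  for (p in s$proteomes$sp1) {
    ad <- registerGroup(register(p)) %in% "AD"
    chars <- strsplit(as.character(p), "")[[1]]
    n <- n + sum(ad)
    k <- k + sum(chars[ad] %in% hyd)
  }
  # 0.8 +- 3 binomial sigma
  expect_lt(abs(k / n - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("realized coiled-coil content is near the spec target", {
  spec <- familySpec(nFamilies = 30L, seed = 29L)
  s <- simulateFamilies(spec)
  frac <- mean(vapply(s$proteomes$sp1, ccContent, 0))
  expect_lt(abs(frac - spec$ccFraction), 0.05)
})

test_that("composition tilts preserve the register-class masses", {
  set.seed(77)
  hyd <- strsplit("LIVMAF", "")[[1]]
  for (i in 1:10) {
    tab <- CoilAlign:::registerFrequencies(0.8)
    expect_equal(sum(tab$AD), 1)
    expect_equal(unname(sum(tab$AD[hyd])), 0.8)  # pinned interface mass
    expect_equal(unname(sum(tab$EG[c("E", "K", "R", "Q", "D")])), 0.7)
  }
  # tilt 0 is the identity
  expect_identical(CoilAlign:::registerFrequencies(0),
                   CoilAlign:::registerFrequencies(0))
})

test_that("gold pairs and decoys are disjoint by construction", {
  s <- simulateFamilies(familySpec(nFamilies = 6L, seed = 4L))
  goldIds <- c(s$gold$id1, s$gold$id2)
  decoys <- grep("^dec", names(s$proteomes$sp2), value = TRUE)
  expect_length(decoys, 6L * 3L)
  expect_length(intersect(goldIds, decoys), 0L)
  # every protein annotated: probabilities only 0.05/0.95, registers
  # labelled inside domains only
  p <- s$proteomes$sp2[[1]]
  expect_setequal(unique(ccProb(p)), c(0.05, 0.95))
  expect_true(all((register(p) != "-") == (ccProb(p) == 0.95)))
})
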