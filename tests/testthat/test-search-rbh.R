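test_that("all-vs-all produces both directions and truncates to topN", {
  # 2 proteomes x 1 protein -> exactly 2 records
  p1 <- heptadProtein("a1", species = "s1")
  p2 <- heptadProtein("b1", species = "s2")
  hits <- allVsAll(list(s1 = list(p1), s2 = list(p2)),
                   alignParams("plain"))
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$query, c("a1", "b1"))
  # identical proteins are each other's top hit with equal bit scores
  expect_equal(hits$bits[1], hits$bits[2])

  expect_error(allVsAll(list(s1 = list(p1)), alignParams("plain")),
               "two proteomes")
  expect_error(allVsAll(list(s1 = list(p1, p1), s2 = list(p2)),
                        alignParams("plain")), "duplicate")
})

test_that("topN truncation keeps the highest scoring subjects", {
  # synthetic hit table path: 1 query vs 60 subjects, topN 50
  set.seed(1)
  sim <- simulateFamilies(familySpec(nFamilies = 1L, seed = 3L))
  q <- sim$proteomes$sp1[[1]]
  subjects <- lapply(1:60, function(i) {
    # longer shared prefix -> strictly higher local alignment score
    CCProtein(sprintf("s%02d", i),
              substr(as.character(q), 1, 30 + 2 * i), species = "s2")
  })
  hits <- allVsAll(list(s1 = list(q),
                        s2 = subjects), alignParams("plain"),
                   topN = 50L)
  got <- hits[hits$query == q@id, ]
  expect_equal(nrow(got), 50L)
  all60 <- CoilAlign:::bestHitScores(list(q), subjects,
                                     alignParams("plain"))
  worst10 <- names(sort(all60[1, ]))[1:10]
  expect_false(any(worst10 %in% got$subject))
})

test_that("reciprocal best hits require mutual unique bests above cutoff", {
  mkHits <- function(...) {
    df <- data.frame(matrix(c(...), ncol = 5, byrow = TRUE),
                     stringsAsFactors = FALSE)
    names(df) <- c("query", "subject", "query_species",
                   "subject_species", "bits")
    df$bits <- as.numeric(df$bits)
    df
  }
  # mutual best 35/32, cutoff 30 -> RBH
  h <- mkHits("x", "y", "s1", "s2", 35, "y", "x", "s2", "s1", 32)
  expect_equal(nrow(reciprocalBestHits(h, 30)), 1L)
  # one side below cutoff -> no RBH
  h2 <- mkHits("x", "y", "s1", "s2", 35, "y", "x", "s2", "s1", 29)
  expect_equal(nrow(reciprocalBestHits(h2, 30)), 0L)
  # tie for x's best -> uniqueness violated, no RBH
  h3 <- mkHits("x", "y", "s1", "s2", 35, "x", "y2", "s1", "s2", 35,
               "y", "x", "s2", "s1", 35, "y2", "x", "s2", "s1", 20)
  expect_equal(nrow(reciprocalBestHits(h3, 30)), 0L)
  # symmetry property: output never depends on direction of listing
  rb <- reciprocalBestHits(h, 30)
  expect_true(all(rb$id1 < rb$id2))
})

test_that("voting keeps pairs supported by at least two methods", {
  pairDf <- function(m) data.frame(id1 = m[, 1], id2 = m[, 2])
  A <- pairDf(rbind(c("p", "q"), c("q", "r")))
  B <- pairDf(rbind(c("q", "p")))           # reversed order, same pair
  C <- pairDf(rbind(c("r", "s")))
  g <- combineVotes(list(blast = A, ccalign = B, ccalignx = C))
  eg <- homologyGraph(g)
  expect_equal(igraph::ecount(eg), 1L)       # only p-q has 2 votes
  expect_equal(igraph::E(eg)$votes, 2L)
  # pair in all three -> votes 3
  g3 <- combineVotes(list(a = A, b = A, c = A))
  expect_true(all(igraph::E(homologyGraph(g3))$votes == 3L))
  # idempotence: votes(S,S,S) keeps exactly S
  expect_equal(igraph::ecount(homologyGraph(g3)), nrow(A))
  expect_error(combineVotes(list(a = A)), "two methods")
})

test_that("betweenness pruning splits bridged groups only", {
  k4 <- function(prefix) t(combn(paste0(prefix, 1:4), 2))
  # barbell: two K4 cliques joined only through v
  edges <- rbind(k4("a"), k4("b"), c("a1", "v"), c("v", "b1"))
  df <- data.frame(id1 = edges[, 1], id2 = edges[, 2])
  g <- combineVotes(list(m1 = df, m2 = df))
  pruned <- pruneSpurious(g)
  grp <- homologyGroups(pruned)
  expect_equal(length(grp), 2L)
  sizes <- sort(unname(vapply(grp, length, 0L)))
  expect_equal(sizes, c(4L, 5L))             # v re-assigned to one side
  expect_equal(igraph::vcount(homologyGraph(pruned)), 9L)

  # double bridge: v plus a direct parallel edge -> group stays intact
  edges2 <- rbind(k4("a"), k4("b"), c("a1", "v"), c("v", "b1"),
                  c("a2", "b2"))
  df2 <- data.frame(id1 = edges2[, 1], id2 = edges2[, 2])
  pruned2 <- pruneSpurious(combineVotes(list(m1 = df2, m2 = df2)))
  expect_equal(length(homologyGroups(pruned2)), 1L)
  expect_equal(igraph::ecount(homologyGraph(pruned2)),
               nrow(edges2))

  # a clique has no high-betweenness bridge: unchanged
  df3 <- data.frame(id1 = t(combn(paste0("c", 1:5), 2))[, 1],
                    id2 = t(combn(paste0("c", 1:5), 2))[, 2])
  pruned3 <- pruneSpurious(combineVotes(list(m1 = df3, m2 = df3)))
  expect_equal(igraph::ecount(homologyGraph(pruned3)), nrow(df3))
})

test_that("group merging respects thresholds and the diameter cap", {
  # two groups, disjoint species, passing score -> merged
  sp <- list(g1 = "s1", g2 = "s2")
  cl <- mergeGroups(data.frame(g1 = "g1", g2 = "g2", score = 5),
                    threshold = 3, strictThreshold = 8,
                    speciesSets = sp)
  expect_equal(cl[["g1"]], cl[["g2"]])
  # overlapping species, score between thresholds -> not merged
  sp2 <- list(g1 = c("s1", "s2"), g2 = c("s2", "s3"))
  cl2 <- mergeGroups(data.frame(g1 = "g1", g2 = "g2", score = 5),
                     threshold = 3, strictThreshold = 8,
                     speciesSets = sp2)
  expect_false(cl2[["g1"]] == cl2[["g2"]])

  # chain g1-g2-...-g6: the diameter-4 cap stops unlimited growth
  chain <- data.frame(g1 = paste0("g", 1:5), g2 = paste0("g", 2:6),
                      score = c(10, 9, 8, 7, 6))
  cl3 <- mergeGroups(chain, threshold = 0, strictThreshold = 0,
                     maxDiameter = 4L)
  # brute-force check: within every cluster, all pairwise chain
  # distances (|i - j|) are <= 4
  for (k in unique(cl3)) {
    members <- as.integer(sub("g", "", names(cl3)[cl3 == k]))
    if (length(members) > 1)
      expect_lte(max(dist(members)), 4)
  }
  expect_gt(length(unique(cl3)), 1L)  # the full chain would span 5
})

test_that("merging is deterministic given distinct scores", {
  pairs <- data.frame(g1 = c("g1", "g3", "g2"),
                      g2 = c("g2", "g4", "g3"),
                      score = c(9, 8, 7))
  cl1 <- mergeGroups(pairs, 0, 0)
  cl2 <- mergeGroups(pairs[c(3, 1, 2), ], 0, 0)
  expect_identical(cl1, cl2[names(cl1)])
})
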