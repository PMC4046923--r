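test_that("coiled-coil excision keeps windows with linkers", {
  # single cc interval [60,120], linker 50, length 300 -> residues
  # 10..170, length 161
  p <- CCProtein("p", paste(rep(strsplit("ARNDCQEGHI", "")[[1]], 30),
                            collapse = ""),
                 ccProb = c(rep(0, 59), rep(0.9, 61), rep(0, 180)))
  art <- makeArtificial(p, 50)
  expect_equal(length(art), 161L)
  expect_equal(as.character(art),
               substr(as.character(p), 10, 170))
  expect_equal(ccProb(art), ccProb(p)[10:170])

  # linker larger than both flanks -> whole protein
  art2 <- makeArtificial(p, 200)
  expect_equal(as.character(art2), as.character(p))

  # overlapping windows merge without duplicating residues
  p3 <- CCProtein("p3", strrep("A", 100),
                  ccProb = c(rep(0, 10), rep(0.9, 10), rep(0, 10),
                             rep(0.9, 10), rep(0, 60)))
  art3 <- makeArtificial(p3, 20)
  expect_equal(length(art3), 60L)  # one window 1..60

  # annotations survive the coordinate map
  expect_equal(register(art3), register(p3)[1:60])

  expect_error(makeArtificial(CCProtein("q", "AAAA"), 10),
               "not a coiled-coil protein")
})

test_that("FDR sweep and recall at the loosest admissible threshold", {
  gold <- data.frame(id1 = sprintf("q%02d", 1:20),
                     id2 = sprintf("t%02d", 1:20))
  # all best hits correct -> fdr 0 everywhere, full recall
  bhAll <- data.frame(query = gold$id1, subject = gold$id2,
                      bits = seq(100, 81))
  evAll <- evaluateBestHits(gold, bhAll, 0.05)
  expect_true(all(evAll$curve$fdr == 0))
  expect_equal(evAll$recallAtFdr, 1)
  # all wrong -> zero recall
  bhWrong <- data.frame(query = gold$id1,
                        subject = rev(gold$id2), bits = seq(100, 81))
  expect_equal(evaluateBestHits(gold, bhWrong, 0.05)$recallAtFdr, 0)

  # 20 predictions: 19 correct (scores 100..82), 1 wrong at 90:
  # at the loosest threshold (82) fdr = 1/20 = 0.05 exactly
  bh <- data.frame(query = gold$id1, subject = gold$id2,
                   bits = c(seq(100, 82), 90))
  bh$subject[20] <- "wrongTarget"
  ev <- evaluateBestHits(gold, bh, 0.05)
  expect_equal(ev$recallAtFdr, 19 / 20)
  # brute-force sweep agreement
  for (r in seq_len(nrow(ev$curve))) {
    t <- ev$curve$threshold[r]
    expect_equal(ev$curve$n_predictions[r], sum(bh$bits >= t))
  }
  # low-count thresholds are suppressed in the curve
  expect_true(all(ev$curve$n_predictions >= 10))
  expect_error(evaluateBestHits(gold[0, ], bh), "empty gold")
  expect_error(evaluateBestHits(gold, rbind(bh, bh[1, ])),
               "one best hit")
})

test_that("recall is monotone non-decreasing in the FDR level", {
  set.seed(31)
  gold <- data.frame(id1 = sprintf("q%02d", 1:30),
                     id2 = sprintf("t%02d", 1:30))
  bh <- data.frame(query = gold$id1,
                   subject = ifelse(stats::runif(30) < 0.7, gold$id2,
                                    "junk"),
                   bits = round(stats::runif(30, 20, 90), 1))
  rec <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                function(a) evaluateBestHits(gold, bh, a)$recallAtFdr, 0)
  expect_true(all(diff(rec) >= 0))
})

test_that("the reciprocal-best-hit recall needs both directions", {
  gold <- data.frame(id1 = c("q1", "q2", "q3"),
                     id2 = c("t1", "t2", "t3"))
  fwd <- data.frame(query = c("q1", "q2", "q3"),
                    subject = c("t1", "t2", "t3"), bits = c(50, 40, 35))
  rev <- data.frame(query = c("t1", "t2", "t3"),
                    subject = c("q1", "q2", "x9"), bits = c(48, 20, 30))
  ev <- evaluateBestHits(gold, fwd, alpha = 0.05,
                         reverseBestHits = rev)
  # q1/t1 mutual above threshold; q2/t2 mutual but reverse score below
  # the loosest admissible threshold (35); q3/t3 not mutual
  expect_equal(ev$rbhRecallAtFdr, 1 / 3)
  expect_true(is.na(evaluateBestHits(gold, fwd)$rbhRecallAtFdr))
})

test_that("method comparison demands one query universe", {
  gold <- data.frame(id1 = c("q1", "q2"), id2 = c("t1", "t2"))
  bh <- data.frame(query = c("q1", "q2"), subject = c("t1", "t2"),
                   bits = c(50, 40))
  out <- compareMethods(list(m1 = bh, m2 = bh), gold)
  expect_equal(out$recallAtFdr[1], out$recallAtFdr[2])  # identical rows
  oracle <- bh  # the gold itself recalls everything
  expect_equal(compareMethods(list(gold = oracle), gold)$recallAtFdr, 1)
  expect_error(compareMethods(list(m1 = bh, m2 = bh[1, ]), gold),
               "universe")
})
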