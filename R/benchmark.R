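#' @include AllClasses.R search.R
NULL

#' Build an artificial coiled-coil protein by excision with linkers
#'
#' Emulates the benchmark construction: every predicted coiled-coil
#' domain is excised together with \code{linker} flanking residues on
#' each side; overlapping windows are merged, and the windows are
#' concatenated in order with all per-residue annotation carried along.
#' Shorter linkers leave less unique non-coiled-coil context and make
#' recognising the true homolog harder.
#'
#' @param p a [CCProtein-class] with at least one coiled-coil interval
#'   at \code{cutoff}.
#' @param linker number of flanking residues kept per side.
#' @param cutoff coiled-coil probability cutoff (default 0.8).
#' @return a [CCProtein-class] (same id and species).
#' @examples
#' p <- CCProtein("p", strrep("A", 300),
#'                ccProb = c(rep(0, 59), rep(0.9, 61), rep(0, 180)))
#' length(makeArtificial(p, 50))  # residues 10..170 -> 161
#' @export
makeArtificial <- function(p, linker, cutoff = 0.8) {
  part <- partitionProtein(p, cutoff)
  if (length(part@ccIntervals) == 0L)
    stop("not a coiled-coil protein")
  n <- length(p)
  win <- IRanges::IRanges(
    start = pmax(1L, IRanges::start(part@ccIntervals) - linker),
    end = pmin(n, IRanges::end(part@ccIntervals) + linker))
  win <- IRanges::reduce(win)
  idx <- unlist(Map(seq.int, IRanges::start(win), IRanges::end(win)))
  chars <- strsplit(p@residues, "")[[1]]
  CCProtein(p@id, paste(chars[idx], collapse = ""),
            ccProb = p@ccProb[idx], register = p@register[idx],
            species = p@species)
}

#' Best-hit correctness curve and recall at an FDR level
#'
#' Sweeps a score threshold over the observed best-hit scores. At each
#' threshold t, the predictions are the queries whose best hit scores
#' at least t; a prediction is correct when the best hit is any
#' annotated ortholog of the query. The FDR at t is
#' 1 - correct/predictions. The headline number is the recall at the
#' loosest threshold with FDR <= \code{alpha}: the fraction of gold
#' pairs recovered there (the fraction of queries answered correctly is
#' reported alongside).
#'
#' @param gold \code{data.frame} with columns \code{id1}, \code{id2}
#'   (unordered ortholog pairs; one-to-many annotation is allowed).
#' @param bestHits \code{data.frame} with columns \code{query},
#'   \code{subject}, \code{bits} (or \code{score}); at most one row per
#'   query.
#' @param alpha FDR level, default 0.05.
#' @param reverseBestHits optional best-hit table for the opposite
#'   search direction; when given, the reciprocal-best-hit variant of
#'   the recall is also computed (gold pairs that are mutual best hits
#'   with both scores above the threshold, over all gold pairs).
#' @return list with \code{curve} (a \code{data.frame} of
#'   \code{threshold}, \code{n_predictions}, \code{n_correct},
#'   \code{fdr}; thresholds with fewer than 10 predictions are
#'   omitted), \code{recallAtFdr} (gold pairs recovered / gold pairs),
#'   \code{recallQueriesAtFdr}, \code{rbhRecallAtFdr} (\code{NA}
#'   without \code{reverseBestHits}), \code{nGold}, and \code{alpha}.
#' @export
evaluateBestHits <- function(gold, bestHits, alpha = 0.05,
                             reverseBestHits = NULL) {
  if (is.null(gold) || nrow(gold) == 0L) stop("empty gold standard")
  if (anyDuplicated(bestHits$query))
    stop("at most one best hit per query")
  score <- if ("bits" %in% names(bestHits)) bestHits$bits else
    bestHits$score
  goldKey <- unique(pairKey(gold$id1, gold$id2))
  correct <- pairKey(bestHits$query, bestHits$subject) %in% goldKey
  thresholds <- sort(unique(score), decreasing = TRUE)
  nPred <- vapply(thresholds, function(t) sum(score >= t), 0L)
  nCorr <- vapply(thresholds, function(t) sum(correct[score >= t]), 0L)
  fdr <- 1 - nCorr / nPred
  ok <- fdr <= alpha + 1e-12   # guard against floating-point dust
  if (any(ok)) {
    t <- min(thresholds[ok])  # loosest admissible threshold
    i <- which(thresholds == t)
    recPairs <- length(unique(
      pairKey(bestHits$query, bestHits$subject)[score >= t & correct])) /
      length(goldKey)
    recQueries <- nCorr[i] / length(goldKey)
  } else {
    recPairs <- 0
    recQueries <- 0
  }
  rbhRec <- NA_real_
  if (!is.null(reverseBestHits) && any(ok)) {
    t <- min(thresholds[ok])
    rev <- reverseBestHits
    revScore <- if ("bits" %in% names(rev)) rev$bits else rev$score
    fwdKey <- pairKey(bestHits$query, bestHits$subject)
    revKey <- pairKey(rev$query, rev$subject)
    mutual <- fwdKey[score >= t] %in% revKey[revScore >= t]
    rbhRec <- length(unique(fwdKey[score >= t][mutual][
      fwdKey[score >= t][mutual] %in% goldKey])) / length(goldKey)
  }
  curve <- data.frame(threshold = thresholds, n_predictions = nPred,
                      n_correct = nCorr, fdr = fdr)
  list(curve = curve[curve$n_predictions >= 10L, , drop = FALSE],
       recallAtFdr = recPairs, recallQueriesAtFdr = recQueries,
       rbhRecallAtFdr = rbhRec, nGold = length(goldKey), alpha = alpha)
}

#' Plot a best-hit correctness curve
#'
#' Number of predictions against the fraction of correct best hits,
#' with a dashed line at the FDR level.
#'
#' @param ev result of [evaluateBestHits()].
#' @param add add to an existing plot.
#' @param col line colour.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the curve \code{data.frame}.
#' @export
plotBenchmarkCurve <- function(ev, add = FALSE, col = "black", ...) {
  cv <- ev$curve
  frac <- 1 - cv$fdr
  if (!add) {
    graphics::plot(cv$n_predictions, frac, type = "s", col = col,
                   xlab = "number of predictions",
                   ylab = "fraction of correct best hits",
                   ylim = c(0, 1), ...)
    graphics::abline(h = 1 - ev$alpha, lty = 2)
  } else {
    graphics::lines(cv$n_predictions, frac, type = "s", col = col)
  }
  invisible(cv)
}

#' Compare alignment methods on one gold standard
#'
#' @param methods named list (method -> best-hit \code{data.frame} as
#'   in [evaluateBestHits()]); all methods must cover the same query
#'   set.
#' @param gold gold-standard pair table.
#' @param alpha FDR level.
#' @return \code{data.frame} with one row per method (\code{method},
#'   \code{recallAtFdr}, \code{recallQueriesAtFdr}), ordered by
#'   decreasing recall.
#' @export
compareMethods <- function(methods, gold, alpha = 0.05) {
  qsets <- lapply(methods, function(m) sort(m$query))
  if (!all(vapply(qsets, identical, TRUE, qsets[[1L]])))
    stop("methods must cover the same query universe")
  rows <- lapply(names(methods), function(nm) {
    ev <- evaluateBestHits(gold, methods[[nm]], alpha)
    data.frame(method = nm, recallAtFdr = ev$recallAtFdr,
               recallQueriesAtFdr = ev$recallQueriesAtFdr)
  })
  out <- do.call(rbind, rows)
  out[order(-out$recallAtFdr), , drop = FALSE]
}

#' Run the synthetic coiled-coil excision benchmark
#'
#' Generates synthetic protein families ([simulateFamilies()]), builds
#' artificial proteins for each linker length ([makeArtificial()]),
#' finds every query's best hit in the other species' database (true
#' homologs plus decoys) under each alignment mode, and evaluates
#' best-hit correctness against the generator's gold standard.
#'
#' @param spec a [familySpec()].
#' @param linkers linker lengths to sweep (default 10, 25, 50, 100).
#' @param modes alignment modes to compare.
#' @param alpha FDR level, default 0.05.
#' @param base base [ScoreMatrix-class].
#' @param verbose print progress.
#' @return \code{data.frame} with columns \code{mode}, \code{linker},
#'   \code{recallAtFdr}, \code{recallQueriesAtFdr}.
#' @export
runBenchmark <- function(spec = familySpec(), linkers = c(10, 25, 50, 100),
                         modes = c("plain", "ccalign", "ccalignx"),
                         alpha = 0.05, base = blosum62(),
                         verbose = FALSE) {
  sim <- simulateFamilies(spec)
  goldIds <- unique(c(sim$gold$id1, sim$gold$id2))
  out <- list()
  for (ell in linkers) {
    queries <- lapply(sim$proteomes[[1L]], makeArtificial, linker = ell)
    queries <- Filter(function(p) p@id %in% goldIds, queries)
    db <- lapply(sim$proteomes[[2L]], makeArtificial, linker = ell)
    for (mode in modes) {
      params <- alignParams(mode)
      bh <- bestHitTable(queries, db, params, base)
      ev <- evaluateBestHits(sim$gold, bh, alpha)
      if (verbose)
        message(sprintf("linker %3d  %-8s recall %.3f", ell, mode,
                        ev$recallAtFdr))
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, linker = ell, recallAtFdr = ev$recallAtFdr,
        recallQueriesAtFdr = ev$recallQueriesAtFdr)
    }
  }
  do.call(rbind, out)
}
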