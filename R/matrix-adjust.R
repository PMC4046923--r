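#' @include AllClasses.R matrix-base.R
NULL

#' Amino-acid composition of a sequence
#'
#' Counts the 20 standard amino acids (\code{X} and other letters are
#' excluded) and blends them with a background distribution through a
#' pseudocount mass: \eqn{f_a = (n_a + m \cdot bg_a) / (n + m)}.
#' The default mass of 20 (one per amino acid) guarantees a strictly
#' positive composition, which the adjustment solver requires; a mass of
#' 0 returns the raw (possibly degenerate) frequencies.
#'
#' @param seq amino-acid string (an empty string returns the background
#'   unchanged).
#' @param pseudoMass non-negative pseudocount mass, default 20.
#' @param background 20-vector of background frequencies (default:
#'   BLOSUM62 background).
#' @return named list with \code{freq} (named 20-vector summing to 1)
#'   and \code{nObs} (number of standard residues counted).
#' @examples
#' computeComposition("ACDE", 20, rep(0.05, 20))$freq[["A"]]  # 2/24
#' @export
computeComposition <- function(seq, pseudoMass = 20,
                               background = blosum62Background()) {
  if (pseudoMass < 0) stop("pseudoMass must be >= 0")
  stopifnot(length(background) == 20L)
  background <- background / sum(background)
  idx <- encodeSequence(cleanSequence(seq))
  cnt <- tabulate(idx[idx < 20L] + 1L, nbins = 20L)
  n <- sum(cnt)
  if (n == 0L && pseudoMass == 0)
    freq <- background
  else
    freq <- (cnt + pseudoMass * background) / (n + pseudoMass)
  list(freq = stats::setNames(freq, AA20), nObs = n)
}

asComposition <- function(x) {
  if (is.list(x)) x <- x$freq
  stopifnot(length(x) == 20L, all(x >= 0))
  x / sum(x)
}

#' Compositionally adjust a substitution matrix at fixed relative entropy
#'
#' Re-derives the joint target distribution of \code{base} for a pair of
#' sequence compositions: the adjusted \eqn{Q} minimises the KL
#' divergence to the base target distribution subject to (i) row
#' marginals equal to \code{c1}, (ii) column marginals equal to
#' \code{c2}, and (iii) relative entropy
#' \eqn{D(Q \| c1 \otimes c2)} equal to the base matrix's entropy.
#' The system is solved by a damped Newton iteration on the Lagrangian
#' stationarity family (with a monotone bisection/Sinkhorn fallback);
#' integer scores are re-derived from \eqn{Q} at the base scale.
#'
#' When the constraints are already satisfied by the base distribution
#' (compositions equal to the base background), the base matrix is
#' returned unchanged. When the solver cannot reach the target entropy
#' (extreme compositions), the base matrix is returned with its
#' \code{fallback} flag set and a warning is issued.
#'
#' @param base a [ScoreMatrix-class] with a valid joint distribution.
#' @param c1,c2 compositions (output of [computeComposition()] or bare
#'   positive 20-vectors), strictly positive.
#' @param tol convergence tolerance on constraint residuals (default
#'   1e-10).
#' @param maxIter maximum Newton iterations (default 100).
#' @return an adjusted [ScoreMatrix-class].
#' @examples
#' b <- blosum62()
#' m <- adjustMatrix(b, computeComposition("LEKLLEKL"),
#'                   computeComposition("LERLIDQL"))
#' relEntropyBits(m) - relEntropyBits(b)  # ~0 by construction
#' @export
adjustMatrix <- function(base, c1, c2, tol = 1e-10, maxIter = 100L) {
  stopifnot(is(base, "ScoreMatrix"))
  c1 <- asComposition(c1)
  c2 <- asComposition(c2)
  if (any(c1 <= 0) || any(c2 <= 0))
    stop("compositions must be strictly positive (use pseudocounts)")
  res <- cpp_adjust_q(base@jointQ, c1, c2, base@relEntropyBits, tol,
                      as.integer(maxIter))
  if (res$noop) return(base)
  if (!res$converged) {
    warning("matrix adjustment did not converge; base matrix returned")
    out <- base
    out@fallback <- TRUE
    return(out)
  }
  q <- res$q
  newScoreMatrix(scoresFromProbs(q, c1, c2, base@scale,
                                 xScores = base@scores),
                 q, c1, c2, scale = base@scale,
                 name = paste0(base@name, ".adj"), adjusted = TRUE)
}

#' Register weights from group entropies
#'
#' Converts relative entropies of register(-group) substitution matrices
#' into multiplicative score weights. Scheme \code{"median"} divides
#' each entropy by the median entropy; \code{"blosum"} divides by the
#' base-matrix entropy \code{hBase}; the \code{per_register_*} variants
#' do the same on per-register entropies (names \code{a}..\code{g});
#' \code{"off"} returns unit weights.
#'
#' @param entropies named positive numeric vector: groups \code{AD},
#'   \code{EG}, \code{BCF} (group schemes) or registers \code{a}..\code{g}
#'   (per-register schemes).
#' @param scheme weighting scheme.
#' @param hBase reference entropy for the \code{blosum} schemes
#'   (default: the shipped BLOSUM62 entropy).
#' @return named numeric vector of weights, same names as
#'   \code{entropies}.
#' @examples
#' computeRegisterWeights(c(AD = 0.45, EG = 0.32, BCF = 0.28), "median")
#' @export
computeRegisterWeights <- function(entropies,
                                   scheme = c("median", "blosum",
                                              "per_register_median",
                                              "per_register_blosum",
                                              "off"),
                                   hBase = NULL) {
  scheme <- match.arg(scheme)
  wanted <- if (startsWith(scheme, "per_register")) REGISTERS else GROUPS
  if (scheme != "off") {
    if (!all(wanted %in% names(entropies)))
      stop("missing entropies for: ",
           paste(setdiff(wanted, names(entropies)), collapse = ", "))
    entropies <- entropies[wanted]
    if (any(entropies <= 0)) stop("entropies must be positive")
  } else {
    entropies <- stats::setNames(rep(1, length(wanted)), wanted)
  }
  w <- switch(scheme,
    off = rep(1, length(wanted)),
    median = entropies / stats::median(entropies),
    per_register_median = entropies / stats::median(entropies),
    blosum = ,
    per_register_blosum = {
      if (is.null(hBase)) hBase <- relEntropyBits(blosum62())
      entropies / hBase
    })
  stats::setNames(as.numeric(w), wanted)
}

# per-register weight vector (length 7, order a..g) for the aligner
regWeightVector <- function(params) {
  scheme <- params@weightsScheme
  if (scheme == "off") return(rep(1, 7))
  w <- computeRegisterWeights(params@groupEntropies, scheme)
  if (startsWith(scheme, "per_register")) as.numeric(w[REGISTERS])
  else as.numeric(w[REGISTER_GROUPS[REGISTERS]])
}

#' Build the per-pair bundle of substitution matrices
#'
#' Implements the per-pair matrix pipeline: both proteins are
#' partitioned at the coiled-coil cutoff, their coiled-coil,
#' non-coiled-coil and full-length subsequence compositions are
#' computed, and the base matrix is compositionally adjusted for each
#' region pair ([adjustMatrix()]). In ccalignx mode, additional matrices
#' are adjusted for the three register groups. Regions shorter than
#' \code{minRegionLen} residues on either side reuse the next-coarser
#' matrix (cc/non-cc fall back to full-length; register groups fall
#' back to the coiled-coil matrix).
#'
#' @param A,B [CCProtein-class] query and subject.
#' @param params an [AlignParams-class].
#' @param base base [ScoreMatrix-class], default [blosum62()].
#' @return a [MatrixSet-class].
#' @export
buildMatrixSet <- function(A, B, params = alignParams(),
                           base = blosum62()) {
  mode <- params@mode
  if (mode == "plain" || !params@adjust) {
    return(new("MatrixSet", mCC = base, mNonCC = base, mFull = base,
               mGroup = list(),
               weights = stats::setNames(rep(1, 3), GROUPS),
               bonus = if (mode == "ccalignx") params@bonus else 0,
               mode = mode))
  }
  subA <- extractSubsequences(A, partitionProtein(A, params@ccCutoff))
  subB <- extractSubsequences(B, partitionProtein(B, params@ccCutoff))
  comp <- function(s) computeComposition(s, params@pseudoMass, base@bgRow)
  minL <- params@minRegionLen
  adjustFor <- function(region, fallbackM) {
    ca <- comp(subA[[region]])
    cb <- comp(subB[[region]])
    if (ca$nObs < minL || cb$nObs < minL) return(fallbackM)
    m <- adjustMatrix(base, ca, cb)
    if (m@fallback) fallbackM else m
  }
  fullA <- comp(A@residues)
  fullB <- comp(B@residues)
  mFull <- if (fullA$nObs < minL || fullB$nObs < minL) base else
    adjustMatrix(base, fullA, fullB)
  mCC <- adjustFor("cc", mFull)
  mNonCC <- adjustFor("noncc", mFull)
  mGroup <- list()
  if (mode == "ccalignx")
    for (g in GROUPS) {
      m <- adjustFor(g, mCC)
      if (!identical(m, mCC)) mGroup[[g]] <- m
    }
  wts <- if (params@weightsScheme == "off")
    stats::setNames(rep(1, 3), GROUPS)
  else {
    w <- computeRegisterWeights(params@groupEntropies,
                                params@weightsScheme)
    if (startsWith(params@weightsScheme, "per_register"))
      stats::setNames(vapply(GROUPS, function(g) {
        stats::median(w[names(REGISTER_GROUPS)[REGISTER_GROUPS == g]])
      }, 0), GROUPS)
    else w[GROUPS]
  }
  new("MatrixSet", mCC = mCC, mNonCC = mNonCC, mFull = mFull,
      mGroup = mGroup, weights = wts,
      bonus = if (mode == "ccalignx") params@bonus else 0, mode = mode)
}

setMethod("show", "MatrixSet", function(object) {
  cat("MatrixSet (mode", object@mode, "):",
      "H(cc) =", sprintf("%.3f", object@mCC@relEntropyBits),
      "H(noncc) =", sprintf("%.3f", object@mNonCC@relEntropyBits),
      "H(full) =", sprintf("%.3f", object@mFull@relEntropyBits),
      "| groups:", length(object@mGroup),
      "| bonus:", object@bonus, "\n")
})
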