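#' @include AllClasses.R matrix-adjust.R
NULL

#' Alignment parameter object
#'
#' Collects every knob of the aligner with the defaults of the method:
#' coiled-coil probability cutoff 0.8, affine gaps 11/1 (the BLAST
#' protein defaults; the first gapped position costs open + extend),
#' register-overlap bonus 1 half-bit (ccalignx), median-normalised
#' register-group weights from the group entropies, and Karlin-Altschul
#' \eqn{\lambda = 0.267}, \eqn{K = 0.041} for bit scores.
#'
#' @param mode \code{"plain"}, \code{"ccalign"} or \code{"ccalignx"}.
#' @param ccCutoff coiled-coil probability cutoff (default 0.8).
#' @param gapOpen,gapExtend affine gap penalties (defaults 11, 1).
#' @param weightsScheme register weighting scheme (default
#'   \code{"median"}); see [computeRegisterWeights()].
#' @param bonus register-overlap bonus in score units (default 1).
#' @param lambda,k bit-score parameters.
#' @param groupEntropies named entropies driving the weights; defaults
#'   to typical register-group entropies (interface 0.45, intermediate
#'   0.32, outside 0.28 bits) estimated from conserved-block data.
#' @param minRegionLen minimum region length for dedicated adjustment
#'   (default 20 residues).
#' @param pseudoMass composition pseudocount mass (default 20).
#' @param confidenceRule \code{"query"} or \code{"max"}; how the
#'   register of a coiled-coil residue pair is picked when both sides
#'   are annotated (the more confident prediction wins; the rule decides
#'   ties).
#' @param adjust disable compositional adjustment when \code{FALSE}.
#' @return an [AlignParams-class].
#' @export
alignParams <- function(mode = c("ccalign", "ccalignx", "plain"),
                        ccCutoff = 0.8, gapOpen = 11L, gapExtend = 1L,
                        weightsScheme = "median", bonus = 1,
                        lambda = 0.267, k = 0.041,
                        groupEntropies = c(AD = 0.45, EG = 0.32,
                                           BCF = 0.28),
                        minRegionLen = 20L, pseudoMass = 20,
                        confidenceRule = c("query", "max"),
                        adjust = TRUE) {
  new("AlignParams", mode = match.arg(mode), ccCutoff = ccCutoff,
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      weightsScheme = weightsScheme, bonus = bonus, lambda = lambda,
      k = k, groupEntropies = groupEntropies,
      minRegionLen = as.integer(minRegionLen), pseudoMass = pseudoMass,
      confidenceRule = match.arg(confidenceRule), adjust = adjust)
}

#' Select the substitution matrix for one residue pair
#'
#' The per-pair rule of the region-aware aligner: both residues
#' coiled-coil selects the coiled-coil matrix (ccalign) or the
#' register-group matrix of the more confident prediction (ccalignx);
#' neither coiled-coil selects the non-coiled-coil matrix; the mixed
#' case selects the full-length matrix. In ccalignx mode a bonus
#' applies iff the two registers are annotated and identical.
#'
#' @param stateI,stateJ logical coiled-coil states of the two residues.
#' @param regI,regJ register labels (\code{"a"}..\code{"g"} or
#'   \code{"-"}).
#' @param probI,probJ coiled-coil probabilities.
#' @param set a [MatrixSet-class] (only its mode/groups are consulted).
#' @param mode alignment mode; defaults to the set's mode.
#' @param confidenceRule see [alignParams()].
#' @return list with \code{tag} (one of CC, NONCC, MIXED, AD, EG, BCF)
#'   and \code{bonusApplies}.
#' @export
selectMatrix <- function(stateI, stateJ, regI, regJ, probI, probJ, set,
                         mode = set@mode, confidenceRule = "query") {
  if (stateI && stateJ) {
    reg <- if (confidenceRule == "query") {
      if (probI >= probJ) regI else regJ
    } else {
      if (probI > probJ) regI
      else if (probJ > probI) regJ
      else sort(c(regI, regJ))[1]
    }
    grp <- registerGroup(reg)
    tag <- if (mode == "ccalignx" && !is.na(grp)) grp else "CC"
    bonus <- mode == "ccalignx" && regI %in% REGISTERS && regI == regJ
    list(tag = tag, bonusApplies = bonus)
  } else if (!stateI && !stateJ) {
    list(tag = "NONCC", bonusApplies = FALSE)
  } else {
    list(tag = "MIXED", bonusApplies = FALSE)
  }
}

# the 10-slot integer matrix bank consumed by the C++ engine
# (0 full, 1 noncc, 2 cc, 3..9 weight-scaled per-register copies)
bankFromSet <- function(set, params, base = blosum62()) {
  if (set@mode == "plain" || !params@adjust)
    return(rep(list(base@scores), 10L))
  wreg <- regWeightVector(params)
  scaled <- function(gov, w) {
    if (w == 1) return(gov@scores)
    scoresFromProbs(gov@jointQ, gov@bgRow, gov@bgCol, scale = 0.5 / w,
                    xScores = base@scores)
  }
  bank <- vector("list", 10L)
  bank[[1L]] <- set@mFull@scores
  bank[[2L]] <- set@mNonCC@scores
  bank[[3L]] <- set@mCC@scores
  for (r in seq_len(7L)) {
    g <- REGISTER_GROUPS[[REGISTERS[r]]]
    gov <- if (set@mode == "ccalignx" && !is.null(set@mGroup[[g]]))
      set@mGroup[[g]] else set@mCC
    bank[[3L + r]] <- scaled(gov, wreg[r])
  }
  bank
}

#' Bit score from a raw alignment score
#'
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}.
#'
#' @param raw raw score(s).
#' @param lambda,k Karlin-Altschul parameters (defaults 0.267, 0.041,
#'   the standard gapped BLOSUM62 values for 11/1 gaps).
#' @return bit score(s).
#' @examples
#' bitScore(50)  # 23.87
#' @export
bitScore <- function(raw, lambda = 0.267, k = 0.041) {
  stopifnot(lambda > 0, k > 0)
  (lambda * raw - log(k)) / log(2)
}

#' Coiled-coil-aware local alignment of two proteins
#'
#' Runs the matrix-switching Smith-Waterman-Gotoh alignment. In
#' \code{"plain"} mode a single fixed matrix scores every pair; in
#' \code{"ccalign"} mode the compositionally adjusted coiled-coil /
#' non-coiled-coil / full-length matrices are switched per residue
#' pair; \code{"ccalignx"} additionally uses register-group matrices
#' and awards a bonus to register-matched pairs. Traceback ties prefer
#' diagonal over up over left.
#'
#' @param A,B [CCProtein-class] query and subject.
#' @param params an [AlignParams-class].
#' @param base base [ScoreMatrix-class].
#' @param set optional pre-built [MatrixSet-class] (rebuilt from the
#'   pair otherwise).
#' @return an [Alignment-class].
#' @examples
#' a <- CCProtein("q", "HEAGAWGHEE")
#' b <- CCProtein("s", "PAWHEAE")
#' ccAlign(a, b, alignParams("plain", gapOpen = 10L))
#' @export
ccAlign <- function(A, B, params = alignParams(), base = blosum62(),
                    set = NULL) {
  if (is.null(set)) set <- buildMatrixSet(A, B, params, base)
  pa <- proteinPayload(A, params)
  pb <- proteinPayload(B, params)
  bank <- bankFromSet(set, params, base)
  res <- cpp_align_full(pa, pb, bank, as.integer(round(params@bonus)),
                        params@mode == "ccalignx",
                        if (params@confidenceRule == "query") 0L else 1L,
                        params@gapOpen, params@gapExtend)
  tags <- slotToTag(res$slot, set@mode)
  pairs <- data.frame(qpos = res$qpos, spos = res$spos, tag = tags,
                      bonus = res$bonus)
  new("Alignment", queryId = A@id, subjectId = B@id,
      rawScore = as.integer(res$score),
      bitScore = bitScore(res$score, params@lambda, params@k),
      qStart = as.integer(res$qstart), qEnd = as.integer(res$qend),
      sStart = as.integer(res$sstart), sEnd = as.integer(res$send),
      pairs = pairs, nBonus = as.integer(sum(res$bonus)))
}

slotToTag <- function(slot, mode) {
  tag <- character(length(slot))
  tag[slot == -1] <- ""
  tag[slot == 0] <- "MIXED"
  tag[slot == 1] <- "NONCC"
  tag[slot == 2] <- "CC"
  reg <- slot >= 3
  if (any(reg)) {
    if (mode == "ccalignx")
      tag[reg] <- unname(REGISTER_GROUPS[REGISTERS[slot[reg] - 2]])
    else
      tag[reg] <- "CC"
  }
  tag
}

setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment %s x %s: raw %d, %.1f bits, q[%d-%d] s[%d-%d], %d pair(s), %d register bonus\n",
              object@queryId, object@subjectId, object@rawScore,
              object@bitScore, object@qStart, object@qEnd, object@sStart,
              object@sEnd, nrow(object@pairs), object@nBonus))
})
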