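#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges
#' @importFrom stats setNames median pbinom runif
#' @importFrom utils read.delim write.table
#' @useDynLib CoilAlign, .registration = TRUE
NULL

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
AA21 <- c(AA20, "X")
REGISTERS <- letters[1:7]
REGISTER_GROUPS <- c(a = "AD", b = "BCF", c = "BCF", d = "AD",
                     e = "EG", f = "BCF", g = "EG")
GROUPS <- c("AD", "EG", "BCF")

#' CCProtein: a protein with per-residue coiled-coil annotation
#'
#' The central input object: an amino-acid sequence together with a
#' per-residue coiled-coil probability (as produced by an external
#' coiled-coil predictor) and a per-residue heptad register label
#' (\code{a}--\code{g}, or \code{"-"} where no register is assigned).
#'
#' @slot id protein identifier.
#' @slot species species identifier.
#' @slot residues amino-acid sequence (20-letter alphabet plus \code{X}).
#' @slot ccProb numeric vector of per-residue coiled-coil probabilities
#'   in \code{[0, 1]}, same length as the sequence.
#' @slot register character vector of per-residue register labels
#'   (\code{"a"}..\code{"g"} or \code{"-"}), same length as the sequence.
#'
#' @seealso [CCProtein()], [partitionProtein()], [ccContent()]
#' @exportClass CCProtein
setClass("CCProtein",
  representation(id = "character", species = "character",
                 residues = "character", ccProb = "numeric",
                 register = "character"))

setValidity("CCProtein", function(object) {
  n <- nchar(object@residues)
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (n == 0L)
    msg <- c(msg, "empty protein")
  if (length(object@ccProb) != n || length(object@register) != n)
    msg <- c(msg, "residues, ccProb and register must have equal length")
  if (length(object@ccProb) && (anyNA(object@ccProb) ||
      any(object@ccProb < 0) || any(object@ccProb > 1)))
    msg <- c(msg, "ccProb must lie in [0, 1]")
  if (length(object@register) &&
      !all(object@register %in% c(REGISTERS, "-")))
    msg <- c(msg, "register labels must be a-g or '-'")
  bad <- setdiff(strsplit(object@residues, "")[[1]], AA21)
  if (length(bad))
    msg <- c(msg, paste0("invalid residue(s): ",
                         paste(unique(bad), collapse = "")))
  if (length(msg)) msg else TRUE
})

#' RegionPartition: coiled-coil / non-coiled-coil intervals of a protein
#'
#' Result of thresholding the per-residue coiled-coil probability: the
#' 1-based closed intervals that are coiled-coil and those that are not.
#' The two sets are disjoint, sorted and jointly cover the protein.
#'
#' @slot ccIntervals an [IRanges::IRanges] of coiled-coil intervals.
#' @slot nonccIntervals an [IRanges::IRanges] of the complement.
#' @slot length protein length the partition refers to.
#' @slot cutoff the probability cutoff used.
#'
#' @seealso [partitionProtein()], [extractSubsequences()]
#' @exportClass RegionPartition
setClass("RegionPartition",
  representation(ccIntervals = "IRanges", nonccIntervals = "IRanges",
                 length = "integer", cutoff = "numeric"))

setValidity("RegionPartition", function(object) {
  iv <- c(object@ccIntervals, object@nonccIntervals)
  if (length(iv) == 0L) return("partition has no intervals")
  covered <- IRanges::coverage(iv, width = object@length)
  if (!all(S4Vectors::runValue(covered) == 1L))
    return("intervals must be disjoint and cover 1..length")
  TRUE
})

#' ScoreMatrix: a substitution matrix with its underlying probabilities
#'
#' A 20x20 integer substitution matrix in half-bit units together with
#' the joint target distribution it is the log-odds of, the two
#' background compositions, and its relative entropy in bits.
#'
#' @slot scores 21x21 integer matrix (20 amino acids plus \code{X});
#'   the \code{X} row/column carries fixed base-matrix scores and is not
#'   part of the probabilistic model.
#' @slot jointQ 20x20 joint target probabilities \eqn{q_{ab}} (sum 1).
#' @slot bgRow,bgCol the two background compositions (row/column
#'   marginals of \code{jointQ}).
#' @slot relEntropyBits relative entropy
#'   \eqn{H = \sum q_{ab} \log_2(q_{ab}/(c1_a c2_b))} in bits.
#' @slot scale bits per score unit (0.5 = half-bit convention).
#' @slot name matrix name.
#' @slot adjusted logical, whether the matrix came out of the
#'   compositional adjuster.
#' @slot fallback logical, \code{TRUE} when the adjuster failed to
#'   converge and the base matrix was returned instead.
#'
#' @seealso [blosum62()], [adjustMatrix()], [matrixRelativeEntropy()]
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(scores = "matrix", jointQ = "matrix",
                 bgRow = "numeric", bgCol = "numeric",
                 relEntropyBits = "numeric", scale = "numeric",
                 name = "character", adjusted = "logical",
                 fallback = "logical"),
  prototype(scale = 0.5, adjusted = FALSE, fallback = FALSE))

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@scores), c(21L, 21L)))
    msg <- c(msg, "scores must be 21x21 (20 amino acids + X)")
  if (!identical(dim(object@jointQ), c(20L, 20L)))
    msg <- c(msg, "jointQ must be 20x20")
  if (abs(sum(object@jointQ) - 1) > 1e-10 || any(object@jointQ < 0))
    msg <- c(msg, "jointQ must be a probability distribution (sum 1, >= 0)")
  if (max(abs(rowSums(object@jointQ) - object@bgRow)) > 1e-6)
    msg <- c(msg, "row sums of jointQ must equal bgRow within 1e-6")
  if (max(abs(colSums(object@jointQ) - object@bgCol)) > 1e-6)
    msg <- c(msg, "column sums of jointQ must equal bgCol within 1e-6")
  if (object@relEntropyBits < 0)
    msg <- c(msg, "relEntropyBits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MatrixSet: the per-pair bundle of substitution matrices
#'
#' Everything the aligner needs to score one ordered pair of proteins:
#' the adjusted coiled-coil, non-coiled-coil and full-length matrices,
#' optional register-group matrices, the register weights and the
#' register-overlap bonus.
#'
#' @slot mCC,mNonCC,mFull [ScoreMatrix-class] objects for the three
#'   region classes.
#' @slot mGroup named list of [ScoreMatrix-class] objects for the
#'   register groups \code{AD}, \code{EG}, \code{BCF} (may be empty for
#'   the plain and ccalign modes).
#' @slot weights named numeric, positive weight per register group
#'   (all 1 when weighting is off).
#' @slot bonus register-overlap bonus in score units (used by the
#'   ccalignx mode only).
#' @slot mode one of \code{"plain"}, \code{"ccalign"}, \code{"ccalignx"}.
#'
#' @seealso [buildMatrixSet()], [ccAlign()]
#' @exportClass MatrixSet
setClass("MatrixSet",
  representation(mCC = "ScoreMatrix", mNonCC = "ScoreMatrix",
                 mFull = "ScoreMatrix", mGroup = "list",
                 weights = "numeric", bonus = "numeric",
                 mode = "character"))

setValidity("MatrixSet", function(object) {
  msg <- character()
  if (!object@mode %in% c("plain", "ccalign", "ccalignx"))
    msg <- c(msg, "mode must be plain, ccalign or ccalignx")
  if (length(object@weights) &&
      (is.null(names(object@weights)) ||
       !all(GROUPS %in% names(object@weights)) || any(object@weights <= 0)))
    msg <- c(msg, "weights must be positive and named AD, EG, BCF")
  if (length(object@bonus) != 1L || object@bonus < 0)
    msg <- c(msg, "bonus must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' AlignParams: alignment parameters
#'
#' @slot mode alignment mode: \code{"plain"} (one fixed matrix),
#'   \code{"ccalign"} (region-switched matrices) or \code{"ccalignx"}
#'   (register-group matrices plus register bonus).
#' @slot ccCutoff coiled-coil probability cutoff (residue is coiled-coil
#'   iff its probability is \code{>= ccCutoff}).
#' @slot gapOpen,gapExtend affine gap parameters; the first gapped
#'   position costs \code{gapOpen + gapExtend}.
#' @slot weightsScheme register weighting scheme, one of \code{"median"},
#'   \code{"blosum"}, \code{"per_register_median"},
#'   \code{"per_register_blosum"}, \code{"off"}.
#' @slot bonus register-overlap bonus in score units (ccalignx only).
#' @slot lambda,k Karlin-Altschul parameters for bit-score conversion.
#' @slot groupEntropies named numeric of register-group relative
#'   entropies (bits) used to derive the weights.
#' @slot minRegionLen minimum residue count for a region to receive its
#'   own compositional adjustment; shorter regions reuse the
#'   next-coarser matrix.
#' @slot pseudoMass pseudocount mass added to compositions.
#' @slot confidenceRule \code{"query"} (ties go to the query residue) or
#'   \code{"max"} (symmetric rule: larger probability wins, ties go to
#'   the lexicographically first group).
#' @slot adjust logical; \code{FALSE} disables compositional adjustment
#'   (every matrix is the base matrix).
#'
#' @seealso [alignParams()], [ccAlign()]
#' @exportClass AlignParams
setClass("AlignParams",
  representation(mode = "character", ccCutoff = "numeric",
                 gapOpen = "integer", gapExtend = "integer",
                 weightsScheme = "character", bonus = "numeric",
                 lambda = "numeric", k = "numeric",
                 groupEntropies = "numeric", minRegionLen = "integer",
                 pseudoMass = "numeric", confidenceRule = "character",
                 adjust = "logical"))

setValidity("AlignParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("plain", "ccalign", "ccalignx"))
    msg <- c(msg, "mode must be plain, ccalign or ccalignx")
  if (object@ccCutoff <= 0 || object@ccCutoff > 1)
    msg <- c(msg, "ccCutoff must be in (0, 1]")
  if (object@gapOpen <= 0L || object@gapExtend <= 0L)
    msg <- c(msg, "gap parameters must be positive")
  if (object@gapExtend > object@gapOpen)
    msg <- c(msg, "gapExtend must not exceed gapOpen")
  if (!object@weightsScheme %in%
      c("median", "blosum", "per_register_median", "per_register_blosum",
        "off"))
    msg <- c(msg, "unknown weights scheme")
  if (object@bonus < 0) msg <- c(msg, "bonus must be >= 0")
  if (object@lambda <= 0 || object@k <= 0)
    msg <- c(msg, "lambda and k must be positive")
  if (length(msg)) msg else TRUE
})

#' Alignment: a local alignment result
#'
#' @slot queryId,subjectId sequence identifiers.
#' @slot rawScore integer raw score (>= 0; 0 means empty alignment).
#' @slot bitScore bit score.
#' @slot qStart,qEnd,sStart,sEnd 1-based inclusive alignment coordinates
#'   (0 for an empty alignment).
#' @slot pairs data.frame of aligned positions with columns
#'   \code{qpos}, \code{spos} (0 = gap), \code{tag} (which matrix scored
#'   the pair: CC, NONCC, MIXED, AD, EG, BCF, or "" for gap columns) and
#'   \code{bonus} (logical, register-overlap bonus applied).
#' @slot nBonus number of register-matched aligned pairs.
#'
#' @seealso [ccAlign()]
#' @exportClass Alignment
setClass("Alignment",
  representation(queryId = "character", subjectId = "character",
                 rawScore = "integer", bitScore = "numeric",
                 qStart = "integer", qEnd = "integer",
                 sStart = "integer", sEnd = "integer",
                 pairs = "data.frame", nBonus = "integer"))

#' HomologyGraph: proteins as nodes, accepted homology links as edges
#'
#' A thin wrapper around an undirected [igraph::igraph] whose vertices
#' are proteins (with a \code{species} attribute) and whose edges carry
#' a \code{weight} (bit score) and a \code{votes} attribute (number of
#' methods supporting the link).
#'
#' @slot graph the underlying igraph object.
#'
#' @seealso [combineVotes()], [pruneSpurious()], [homologyGroups()]
#' @exportClass HomologyGraph
setClass("HomologyGraph", representation(graph = "ANY"))

setValidity("HomologyGraph", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
  if (igraph::is_directed(object@graph)) return("graph must be undirected")
  TRUE
})
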