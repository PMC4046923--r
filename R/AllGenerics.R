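#' @include AllClasses.R
NULL

#' Accessors for annotated proteins
#'
#' @param x a [CCProtein-class].
#' @return \code{ccProb}: numeric vector of per-residue coiled-coil
#'   probabilities; \code{register}: character vector of register
#'   labels; \code{species}: the species string.
#' @name protein-accessors
#' @export
setGeneric("ccProb", function(x) standardGeneric("ccProb"))

#' @rdname protein-accessors
#' @export
setGeneric("register", function(x) standardGeneric("register"))

#' @rdname protein-accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' Accessors for substitution matrices
#'
#' @param x a [ScoreMatrix-class].
#' @return \code{scores}: the 21x21 integer score matrix;
#'   \code{jointQ}: the 20x20 joint target distribution;
#'   \code{relEntropyBits}: its relative entropy in bits.
#' @name matrix-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname matrix-accessors
#' @export
setGeneric("jointQ", function(x) standardGeneric("jointQ"))

#' @rdname matrix-accessors
#' @export
setGeneric("relEntropyBits", function(x) standardGeneric("relEntropyBits"))

#' Groups of a homology graph
#'
#' @param x a [HomologyGraph-class].
#' @return named list of character vectors: the connected components
#'   (groups of homologs).
#' @export
setGeneric("homologyGroups", function(x) standardGeneric("homologyGroups"))
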