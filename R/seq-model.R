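#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an annotated protein
#'
#' @param id protein identifier.
#' @param residues amino-acid sequence (string). Lower case is accepted
#'   and upper-cased; \code{U} and \code{O} are mapped to \code{X};
#'   \code{*} is stripped.
#' @param ccProb per-residue coiled-coil probability; a single value is
#'   recycled. Default 0 (no coiled coil).
#' @param register per-residue heptad register label (\code{"a"} to
#'   \code{"g"}, \code{"-"} for none); a single value is recycled.
#' @param species species identifier.
#'
#' @return a [CCProtein-class] object.
#' @examples
#' p <- CCProtein("p1", "MKELEDKIEELLSKAAA",
#'                ccProb = c(rep(0.05, 3), rep(0.95, 14)),
#'                register = c(rep("-", 3), rep(letters[1:7], 2)))
#' ccContent(p)
#' @export
CCProtein <- function(id, residues, ccProb = 0, register = "-",
                      species = "unknown") {
  residues <- cleanSequence(residues)
  n <- nchar(residues)
  if (n == 0L) stop("empty protein")
  if (length(ccProb) == 1L) ccProb <- rep(ccProb, n)
  if (length(register) == 1L) register <- rep(register, n)
  new("CCProtein", id = as.character(id), species = as.character(species),
      residues = residues, ccProb = as.numeric(ccProb),
      register = as.character(register))
}

cleanSequence <- function(x) {
  x <- toupper(gsub("*", "", x, fixed = TRUE))
  if (grepl("[UO]", x)) {
    warning("selenocysteine/pyrrolysine mapped to X")
    x <- chartr("UO", "XX", x)
  }
  x
}

setMethod("ccProb", "CCProtein", function(x) x@ccProb)
setMethod("register", "CCProtein", function(x) x@register)
setMethod("species", "CCProtein", function(x) x@species)
setMethod("length", "CCProtein", function(x) nchar(x@residues))

#' @rdname CCProtein
#' @export
setMethod("as.character", "CCProtein", function(x) x@residues)

setMethod("show", "CCProtein", function(object) {
  n <- length(object)
  cat("CCProtein", object@id, "(", object@species, "),", n, "aa,",
      sprintf("%.1f%%", 100 * mean(object@ccProb >= 0.8)),
      "coiled-coil at p>=0.8\n")
})

#' Map heptad registers to register groups
#'
#' Registers \code{a}, \code{d} form the hydrophobic interface
#' (\code{AD}); \code{e}, \code{g} are the intermediate, often charged
#' positions (\code{EG}); \code{b}, \code{c}, \code{f} face the solvent
#' (\code{BCF}).
#'
#' @param reg character vector of register labels (\code{a}-\code{g};
#'   anything else maps to \code{NA}).
#' @return character vector of group labels.
#' @examples
#' registerGroup(c("a", "e", "f", "-"))
#' @export
registerGroup <- function(reg) {
  unname(REGISTER_GROUPS[match(reg, names(REGISTER_GROUPS))])
}

#' Partition a protein into coiled-coil and non-coiled-coil intervals
#'
#' A residue is coiled-coil iff its predicted probability is greater
#' than or equal to \code{cutoff}. Runs of equal state become 1-based
#' closed intervals.
#'
#' @param p a [CCProtein-class].
#' @param cutoff probability cutoff in (0, 1]; default 0.8.
#' @return a [RegionPartition-class].
#' @examples
#' p <- CCProtein("p", "AAAALLLLLAALLLAA",
#'                ccProb = c(rep(0, 4), rep(0.9, 5), 0, 0, rep(0.9, 3), 0, 0))
#' partitionProtein(p)
#' @export
partitionProtein <- function(p, cutoff = 0.8) {
  stopifnot(is(p, "CCProtein"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- length(p)
  if (n == 0L) stop("empty protein")
  mask <- p@ccProb >= cutoff
  cc <- maskToIntervals(mask)
  noncc <- maskToIntervals(!mask)
  new("RegionPartition", ccIntervals = cc, nonccIntervals = noncc,
      length = n, cutoff = cutoff)
}

maskToIntervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  IRanges::IRanges(start = starts[keep], end = ends[keep])
}

intervalsToMask <- function(iv, n) {
  mask <- logical(n)
  if (length(iv))
    mask[unlist(Map(seq.int, IRanges::start(iv), IRanges::end(iv)))] <- TRUE
  mask
}

#' @rdname RegionPartition-class
#' @param x a \code{RegionPartition}.
#' @export
ccIntervals <- function(x) x@ccIntervals

#' @rdname RegionPartition-class
#' @export
nonccIntervals <- function(x) x@nonccIntervals

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition over", object@length, "residues (cutoff",
      object@cutoff, "):", length(object@ccIntervals), "cc interval(s),",
      length(object@nonccIntervals), "non-cc interval(s)\n")
})

#' Fill missing registers inside coiled-coil runs
#'
#' A coiled-coil residue without a register label (a predictor gap)
#' inherits the register of the nearest coiled-coil residue that has
#' one, within the same coiled-coil interval; ties go to the left
#' neighbour. Residues in intervals with no labelled residue keep
#' \code{"-"}.
#'
#' @param p a [CCProtein-class].
#' @param part a [RegionPartition-class] for \code{p} (defaults to
#'   partitioning at 0.8).
#' @return character vector of effective registers, one per residue;
#'   non-coiled-coil positions are \code{"-"}.
#' @export
effectiveRegister <- function(p, part = partitionProtein(p)) {
  n <- length(p)
  out <- rep("-", n)
  reg <- p@register
  iv <- part@ccIntervals
  for (k in seq_along(iv)) {
    idx <- seq.int(IRanges::start(iv)[k], IRanges::end(iv)[k])
    r <- reg[idx]
    known <- which(r %in% REGISTERS)
    if (length(known) == 0L) next
    if (length(known) < length(r)) {
      for (i in seq_along(r)) {
        if (!r[i] %in% REGISTERS) {
          d <- abs(known - i)
          # ties broken towards the left neighbour
          r[i] <- r[known[which.min(d + (known > i) * 0.5)]]
        }
      }
    }
    out[idx] <- r
  }
  out
}

#' Extract concatenated region subsequences
#'
#' Concatenates the residues of the coiled-coil intervals, of the
#' non-coiled-coil intervals, and of the three register groups (using
#' effective registers, see [effectiveRegister()]), each in sequence
#' order.
#'
#' @param p a [CCProtein-class].
#' @param part a [RegionPartition-class] consistent with \code{p}.
#' @return named list of strings \code{cc}, \code{noncc}, \code{AD},
#'   \code{EG}, \code{BCF}. A coiled-coil residue without any register
#'   in reach stays in \code{cc} but in no group (a warning is issued).
#' @examples
#' p <- CCProtein("p", "LIEKLASLIEKLAS", ccProb = 0.95,
#'                register = rep(letters[1:7], 2))
#' extractSubsequences(p, partitionProtein(p))
#' @export
extractSubsequences <- function(p, part = partitionProtein(p)) {
  if (part@length != length(p))
    stop("partition is not consistent with the protein")
  chars <- strsplit(p@residues, "")[[1]]
  ccMask <- intervalsToMask(part@ccIntervals, part@length)
  eff <- effectiveRegister(p, part)
  grp <- registerGroup(eff)
  if (any(ccMask & is.na(grp)))
    warning(sprintf("%s: %d coiled-coil residue(s) carry no register",
                    p@id, sum(ccMask & is.na(grp))))
  list(cc = paste(chars[ccMask], collapse = ""),
       noncc = paste(chars[!ccMask], collapse = ""),
       AD = paste(chars[ccMask & grp %in% "AD"], collapse = ""),
       EG = paste(chars[ccMask & grp %in% "EG"], collapse = ""),
       BCF = paste(chars[ccMask & grp %in% "BCF"], collapse = ""))
}

#' Fraction of residues in coiled-coils
#'
#' The fraction of residues whose coiled-coil probability is at least
#' \code{cutoff}. Proteins with \code{ccContent() >= 0.20} are
#' conventionally categorised as coiled-coil proteins.
#'
#' @param p a [CCProtein-class].
#' @param cutoff probability cutoff, default 0.8.
#' @return a fraction in \code{[0, 1]}.
#' @export
ccContent <- function(p, cutoff = 0.8) {
  mean(p@ccProb >= cutoff)
}

# integer encoding used by the C++ engine: 0..19 = AA20, 20 = X
encodeSequence <- function(seq) {
  match(strsplit(seq, "")[[1]], AA21) - 1L
}

# per-protein annotation bundle consumed by the C++ aligner
proteinPayload <- function(p, params) {
  part <- partitionProtein(p, params@ccCutoff)
  eff <- effectiveRegister(p, part)
  grp <- registerGroup(eff)
  grpIdx <- match(grp, GROUPS)
  grpIdx[is.na(grpIdx)] <- 0L
  seqIdx <- encodeSequence(p@residues)
  state <- as.integer(p@ccProb >= params@ccCutoff)
  regIdx <- match(eff, REGISTERS)
  regIdx[is.na(regIdx)] <- 0L
  counts <- regionCounts(seqIdx, state, grpIdx)
  list(id = p@id, species = p@species, seq = seqIdx, state = state,
       group = grpIdx, reg = as.integer(regIdx), prob = p@ccProb,
       counts = counts)
}

# residue counts (20-vector, X excluded) for regions full/cc/noncc/AD/EG/BCF
regionCounts <- function(seqIdx, state, grpIdx) {
  std <- seqIdx < 20L
  cnt <- function(sel) tabulate(seqIdx[sel & std] + 1L, nbins = 20L)
  cbind(full = cnt(rep(TRUE, length(seqIdx))),
        cc = cnt(state == 1L), noncc = cnt(state == 0L),
        AD = cnt(state == 1L & grpIdx == 1L),
        EG = cnt(state == 1L & grpIdx == 2L),
        BCF = cnt(state == 1L & grpIdx == 3L))
}
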