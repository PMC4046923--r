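#' @include AllClasses.R align.R
NULL

# run the batch C++ search of a query list against a subject list and
# return the raw score matrix (rows = queries, cols = subjects)
bestHitScores <- function(queries, subjects, params, base = blosum62()) {
  modeI <- match(params@mode, c("plain", "ccalign", "ccalignx")) - 1L
  pq <- lapply(queries, proteinPayload, params = params)
  ps <- lapply(subjects, proteinPayload, params = params)
  raw <- cpp_best_hits(pq, ps, modeI, base@jointQ, base@bgRow,
                       base@relEntropyBits, base@scores,
                       regWeightVector(params),
                       as.integer(round(params@bonus)),
                       if (params@confidenceRule == "query") 0L else 1L,
                       params@gapOpen, params@gapExtend,
                       params@pseudoMass, params@minRegionLen,
                       1e-10, 100L)
  dimnames(raw) <- list(vapply(queries, function(p) p@id, ""),
                        vapply(subjects, function(p) p@id, ""))
  raw
}

# best hit (highest bit score, ties by subject id) of every query
bestHitTable <- function(queries, subjects, params, base = blosum62()) {
  raw <- bestHitScores(queries, subjects, params, base)
  ord <- order(colnames(raw))
  best <- apply(raw[, ord, drop = FALSE], 1L, which.max)
  data.frame(query = rownames(raw), subject = colnames(raw)[ord][best],
             raw = raw[cbind(seq_len(nrow(raw)), ord[best])],
             bits = bitScore(raw[cbind(seq_len(nrow(raw)), ord[best])],
                             params@lambda, params@k),
             row.names = NULL)
}

#' All-vs-all search between annotated proteomes
#'
#' Aligns every protein against every protein of every other species
#' and keeps, per query and target species, the \code{topN} hits with
#' the highest bit scores (ties broken by subject id). Mirrors the
#' truncation used in large-scale ortholog searches (top 50 hits per
#' species).
#'
#' @param proteomes named list (species -> list of
#'   [CCProtein-class]); at least two species.
#' @param params an [AlignParams-class].
#' @param base base [ScoreMatrix-class].
#' @param topN hits kept per (query, target species); default 50.
#' @return a hit table \code{data.frame} with columns \code{query},
#'   \code{subject}, \code{query_species}, \code{subject_species},
#'   \code{raw}, \code{bits}.
#' @export
allVsAll <- function(proteomes, params = alignParams(),
                     base = blosum62(), topN = 50L) {
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes))))
    stop("proteomes must be a named list (names = species)")
  ids <- unlist(lapply(proteomes, vapply, function(p) p@id, ""))
  if (anyDuplicated(ids)) stop("duplicate protein ids across proteomes")
  out <- list()
  for (qs in names(proteomes)) for (ss in names(proteomes)) {
    if (qs == ss) next
    raw <- bestHitScores(proteomes[[qs]], proteomes[[ss]], params, base)
    bits <- bitScore(raw, params@lambda, params@k)
    for (i in seq_len(nrow(raw))) {
      ord <- order(-bits[i, ], colnames(raw))
      keep <- ord[seq_len(min(topN, length(ord)))]
      out[[length(out) + 1L]] <- data.frame(
        query = rownames(raw)[i], subject = colnames(raw)[keep],
        query_species = qs, subject_species = ss,
        raw = raw[i, keep], bits = bits[i, keep], row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Reciprocal best hits from a hit table
#'
#' A pair (x in species 1, y in species 2) is a reciprocal best hit iff
#' y is x's unique best hit in species 2, x is y's unique best hit in
#' species 1, and both bit scores reach \code{bitCutoff}. An exact
#' bit-score tie for a query's best hit disqualifies that query
#' (conservative uniqueness rule).
#'
#' @param hits hit table as returned by [allVsAll()].
#' @param bitCutoff minimum bit score (default 30).
#' @return \code{data.frame} with columns \code{id1}, \code{id2},
#'   \code{species1}, \code{species2}, \code{bits} (the smaller of the
#'   two direction scores); each unordered pair appears once with
#'   \code{id1 < id2}.
#' @export
reciprocalBestHits <- function(hits, bitCutoff = 30) {
  bestOf <- function(df) {
    # unique best hit per (query, subject_species); ties disqualify
    out <- list()
    for (key in unique(paste(df$query, df$subject_species))) {
      sub <- df[paste(df$query, df$subject_species) == key, , drop = FALSE]
      mx <- max(sub$bits)
      top <- sub[sub$bits == mx, , drop = FALSE]
      if (nrow(top) == 1L) out[[length(out) + 1L]] <- top
    }
    do.call(rbind, out)
  }
  best <- bestOf(hits)
  best <- best[best$bits >= bitCutoff, , drop = FALSE]
  if (is.null(best) || nrow(best) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      species1 = character(), species2 = character(),
                      bits = numeric()))
  key <- paste(best$query, best$subject)
  rev <- paste(best$subject, best$query)
  mutual <- best[key %in% rev, , drop = FALSE]
  keep <- mutual$query < mutual$subject
  fwd <- mutual[keep, , drop = FALSE]
  bwd <- mutual[!keep, , drop = FALSE]
  m <- match(paste(fwd$query, fwd$subject), paste(bwd$subject, bwd$query))
  data.frame(id1 = fwd$query, id2 = fwd$subject,
             species1 = fwd$query_species, species2 = fwd$subject_species,
             bits = pmin(fwd$bits, bwd$bits[m]), row.names = NULL)
}
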