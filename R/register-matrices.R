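#' @include AllClasses.R matrix-base.R
NULL

#' Read gapless aligned blocks with register labels
#'
#' Plain-text format: each block is a header line starting with
#' \code{>}, followed by one gapless aligned sequence per line, closed
#' by a register line starting with \code{=} that labels every column
#' with its heptad register (\code{a}-\code{g}).
#'
#' @param path file path.
#' @return list of blocks; each block is a list with \code{id},
#'   \code{seqs} (character vector) and \code{registers} (character
#'   vector, one label per column).
#' @export
readBlocks <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$registers))
      stop("block ", cur$id, " has no register line")
    if (length(unique(nchar(cur$seqs))) != 1L ||
        nchar(cur$seqs[1]) != length(cur$registers))
      stop("block ", cur$id, " rows/registers have unequal width")
    cur
  }
  for (l in lines) {
    if (startsWith(l, ">")) {
      blocks <- c(blocks, list(flush(cur)))
      cur <- list(id = sub("^>\\s*", "", l), seqs = character(0),
                  registers = NULL)
    } else if (startsWith(l, "=")) {
      cur$registers <- strsplit(gsub("[=\\s ]", "", l), "")[[1]]
    } else {
      cur$seqs <- c(cur$seqs, toupper(l))
    }
  }
  blocks <- c(blocks, list(flush(cur)))
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("no blocks found in ", path)
  for (b in blocks)
    if (!all(b$registers %in% REGISTERS))
      stop("block ", b$id, " has non a-g register labels")
  blocks
}

# single-linkage clustering of block rows at a %-identity threshold;
# returns cluster index per row
clusterRows <- function(seqs, identity) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  cl <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (mean(mat[i, ] == mat[j, ]) >= identity) {
      old <- cl[j]
      cl[cl == old] <- cl[i]
    }
  }
  match(cl, unique(cl))
}

#' Register-group substitution matrices from conserved blocks
#'
#' BLOSUM-style construction restricted to heptad-register columns:
#' sequences within each block are clustered at
#' \code{clusteringIdentity} (single linkage) and weighted
#' 1/cluster-size; residue pairs are counted between clusters within
#' each column whose register belongs to the group; counts are
#' symmetrised and normalised into a joint distribution from which
#' half-bit scores and the relative entropy are derived.
#'
#' @param blocks list of blocks as returned by [readBlocks()].
#' @param clusteringIdentity clustering threshold (default 0.62).
#' @param minPairs minimum (weighted) pair observations per group;
#'   fewer raise an error (default 50).
#' @param pseudoPairs total pseudo-pair mass spread over cells by the
#'   background product, keeping all frequencies positive (default 1).
#' @param background background used for the pseudo-pairs.
#' @return named list \code{AD}, \code{EG}, \code{BCF} of
#'   [ScoreMatrix-class] objects.
#' @examples
#' path <- system.file("extdata", "register_blocks_synthetic.txt",
#'                     package = "CoilAlign")
#' ents <- vapply(buildRegisterMatrices(readBlocks(path)),
#'                relEntropyBits, 0)
#' ents["AD"] > ents["EG"]  # interface more informative
#' @export
buildRegisterMatrices <- function(blocks, clusteringIdentity = 0.62,
                                  minPairs = 50,
                                  pseudoPairs = 1,
                                  background = blosum62Background()) {
  counts <- lapply(GROUPS, function(g) matrix(0, 20L, 20L,
                                              dimnames = list(AA20, AA20)))
  names(counts) <- GROUPS
  for (b in blocks) {
    cl <- clusterRows(b$seqs, clusteringIdentity)
    w <- 1 / table(cl)[as.character(cl)]
    mat <- do.call(rbind, strsplit(b$seqs, ""))
    grp <- unname(REGISTER_GROUPS[b$registers])
    for (col in seq_along(b$registers)) {
      g <- grp[col]
      aas <- mat[, col]
      keep <- aas %in% AA20
      if (sum(keep) < 2L) next
      idx <- match(aas[keep], AA20)
      ww <- as.numeric(w[keep])
      cc <- cl[keep]
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i < j && cc[i] != cc[j])
          counts[[g]][idx[i], idx[j]] <-
            counts[[g]][idx[i], idx[j]] + ww[i] * ww[j]
      }
    }
  }
  out <- list()
  for (g in GROUPS) {
    cnt <- counts[[g]]
    tot <- sum(cnt)
    if (tot < minPairs)
      stop("insufficient counts for group ", g,
           sprintf(" (%.1f weighted pairs < %s)", tot, minPairs))
    cnt <- (cnt + t(cnt)) / 2
    q <- cnt / sum(cnt)
    bgq <- outer(background, background)
    q <- (1 - pseudoPairs / (tot + pseudoPairs)) * q +
      (pseudoPairs / (tot + pseudoPairs)) * bgq
    q <- q / sum(q)
    out[[g]] <- newScoreMatrix(
      scoresFromProbs(q, rowSums(q), colSums(q)), q, rowSums(q),
      colSums(q), name = paste0("register.", g))
  }
  out
}
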