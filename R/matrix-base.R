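#' @include AllClasses.R
NULL

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix format (comment lines
#' starting with \code{#}, a header row of residue letters, one labelled
#' row per residue). Only the 20 standard amino acids and \code{X} are
#' retained. If a sidecar file \code{<path>.qij.tsv} exists (as written
#' by [writeScoreMatrix()] with \code{sidecar = TRUE}) the joint target
#' frequencies and compositions are read from it; otherwise the matrix
#' probabilities are reconstructed by inverting the half-bit log-odds
#' against the supplied background and projecting onto its marginals.
#'
#' @param path file path.
#' @param background optional 20-vector of background frequencies used
#'   when no sidecar is present (default: BLOSUM62 background).
#' @param name matrix name (default: file name).
#' @return a [ScoreMatrix-class].
#' @export
readScoreMatrix <- function(path, background = NULL, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  body <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rowLetters <- vapply(body, `[`, "", 1L)
  vals <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  rownames(vals) <- rowLetters
  colnames(vals) <- header
  if (!all(AA21 %in% rownames(vals)) || !all(AA21 %in% colnames(vals)))
    stop("matrix file must cover the 20 standard amino acids and X")
  sc <- matrix(as.integer(round(vals[AA21, AA21])), 21L, 21L,
               dimnames = list(AA21, AA21))
  sidecar <- paste0(path, ".qij.tsv")
  if (file.exists(sidecar)) {
    sd <- readQijSidecar(sidecar)
    q <- sd$q; c1 <- sd$c1; c2 <- sd$c2
  } else {
    if (is.null(background)) background <- blosum62Background()
    c1 <- c2 <- background
    q <- impliedJointQ(sc[AA20, AA20], c1, c2)
  }
  newScoreMatrix(sc, q, c1, c2, name = name)
}

newScoreMatrix <- function(scores, q, c1, c2, scale = 0.5, name = "matrix",
                           adjusted = FALSE, fallback = FALSE) {
  dimnames(scores) <- list(AA21, AA21)
  dimnames(q) <- list(AA20, AA20)
  new("ScoreMatrix", scores = scores, jointQ = q,
      bgRow = rowSums(q), bgCol = colSums(q),
      relEntropyBits = matrixRelativeEntropy(q, rowSums(q), colSums(q)),
      scale = scale, name = name, adjusted = adjusted, fallback = fallback)
}

# invert rounded half-bit log-odds and project to the background marginals
impliedJointQ <- function(sc20, c1, c2) {
  q0 <- outer(c1, c2) * 2^(sc20 * 0.5)
  res <- cpp_sinkhorn(q0 / sum(q0), c1, c2, 1e-12, 10000L)
  res$q
}

#' Write a substitution matrix in NCBI text format
#'
#' @param m a [ScoreMatrix-class].
#' @param path output path.
#' @param sidecar if \code{TRUE}, also write \code{<path>.qij.tsv}
#'   holding the joint target frequencies and the two compositions, so
#'   that [readScoreMatrix()] can round-trip the full object.
#' @param comments optional character vector of comment lines.
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrix <- function(m, path, sidecar = FALSE, comments = NULL) {
  stopifnot(is(m, "ScoreMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(paste("#  Matrix:", m@name, " relative entropy (bits):",
                   format(m@relEntropyBits, digits = 6)), con)
  writeLines(paste0("   ", paste(sprintf("%3s", AA21), collapse = "")), con)
  for (a in AA21)
    writeLines(paste0(a, "  ", paste(sprintf("%3d", m@scores[a, ]),
                                     collapse = "")), con)
  if (sidecar) writeQijSidecar(m, paste0(path, ".qij.tsv"))
  invisible(path)
}

writeQijSidecar <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# joint target frequencies q_ab and compositions", con)
  writeLines(paste(c("", AA20), collapse = "\t"), con)
  for (i in seq_len(20L))
    writeLines(paste(c(AA20[i], sprintf("%.12g", m@jointQ[i, ])),
                     collapse = "\t"), con)
  writeLines(paste(c("bgRow", sprintf("%.12g", m@bgRow)), collapse = "\t"),
             con)
  writeLines(paste(c("bgCol", sprintf("%.12g", m@bgCol)), collapse = "\t"),
             con)
  invisible(path)
}

readQijSidecar <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", row.names = 1L,
                           check.names = FALSE)
  q <- as.matrix(tab[AA20, AA20])
  dimnames(q) <- list(AA20, AA20)
  list(q = q, c1 = as.numeric(tab["bgRow", AA20]),
       c2 = as.numeric(tab["bgCol", AA20]))
}

#' The shipped BLOSUM62 base matrix
#'
#' Loads the BLOSUM62 substitution matrix shipped with the package: the
#' published integer scores (half-bit units) together with the standard
#' public table of count-derived joint target frequencies at 4-decimal
#' precision (normalised to sum 1; the background composition is its
#' marginals). Its relative entropy evaluates to 0.70 bits (2 d.p.).
#'
#' @return a [ScoreMatrix-class].
#' @examples
#' b <- blosum62()
#' round(relEntropyBits(b), 2)
#' @export
blosum62 <- function() {
  cached <- .pkgCache$blosum62
  if (!is.null(cached)) return(cached)
  scPath <- system.file("extdata", "BLOSUM62.txt", package = "CoilAlign")
  qPath <- system.file("extdata", "blosum62_qij.tsv", package = "CoilAlign")
  lines <- readLines(scPath)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  parts <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  sc <- do.call(rbind, lapply(parts, function(x) as.numeric(x[-1])))
  rownames(sc) <- vapply(parts, `[`, "", 1L)
  colnames(sc) <- header
  sc21 <- matrix(as.integer(sc[AA21, AA21]), 21L, 21L,
                 dimnames = list(AA21, AA21))
  qtab <- utils::read.delim(qPath, comment.char = "#", row.names = 1L,
                            check.names = FALSE)
  q <- as.matrix(qtab[AA20, AA20])
  q <- (q + t(q)) / 2          # enforce exact symmetry
  q <- q / sum(q)
  m <- newScoreMatrix(sc21, q, rowSums(q), colSums(q), name = "BLOSUM62")
  assign("blosum62", m, envir = .pkgCache)
  m
}

blosum62Background <- function() blosum62()@bgRow

.pkgCache <- new.env(parent = emptyenv())

#' Relative entropy of a substitution matrix
#'
#' \eqn{H = \sum_{ab} q_{ab} \log_2( q_{ab} / (c1_a c2_b) )} in bits.
#' Cells with \eqn{q_{ab} = 0} contribute 0 (limit convention).
#'
#' @param jointQ 20x20 joint target probabilities (or a
#'   [ScoreMatrix-class], in which case the other arguments are taken
#'   from it).
#' @param c1,c2 background compositions.
#' @return relative entropy in bits (non-negative).
#' @examples
#' q <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
#' matrixRelativeEntropy(q, c(0.5, 0.5), c(0.5, 0.5))  # 0.278 bits
#' @export
matrixRelativeEntropy <- function(jointQ, c1 = NULL, c2 = NULL) {
  if (is(jointQ, "ScoreMatrix")) {
    c1 <- jointQ@bgRow; c2 <- jointQ@bgCol; jointQ <- jointQ@jointQ
  }
  e <- outer(c1, c2)
  nz <- jointQ > 0
  sum(jointQ[nz] * log2(jointQ[nz] / e[nz]))
}

# integer scores from a joint distribution at the given scale (bits per
# unit); round-half-away-from-zero so that -0.5 -> -1 and 0.5 -> 1
scoresFromProbs <- function(q, c1, c2, scale = 0.5, xScores = NULL) {
  lo <- log2(q / outer(c1, c2)) / scale
  lo[q == 0] <- -Inf
  sc <- sign(lo) * floor(abs(lo) + 0.5)
  minSc <- min(sc[is.finite(sc)])
  sc[!is.finite(sc)] <- minSc
  out <- matrix(0L, 21L, 21L, dimnames = list(AA21, AA21))
  out[1:20, 1:20] <- as.integer(sc)
  if (is.null(xScores)) xScores <- blosum62()@scores
  out["X", ] <- xScores["X", AA21]
  out[, "X"] <- xScores[AA21, "X"]
  out
}

setMethod("scores", "ScoreMatrix", function(x) x@scores)
setMethod("jointQ", "ScoreMatrix", function(x) x@jointQ)
setMethod("relEntropyBits", "ScoreMatrix", function(x) x@relEntropyBits)

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix", object@name,
      sprintf("(%s, H = %.4f bits, scale %.2g bits/unit)\n",
              if (object@adjusted) "adjusted" else "base",
              object@relEntropyBits, object@scale))
  if (object@fallback)
    cat("  [adjustment did not converge; base matrix returned]\n")
})
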