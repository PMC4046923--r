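#' @include AllClasses.R seq-model.R
NULL

#' Read proteins from FASTA, optionally with coiled-coil annotation
#'
#' Sequences are upper-cased, \code{*} is stripped, and U/O are mapped
#' to X with a warning. Duplicate ids and empty files are errors. When
#' a coiled-coil annotation table is supplied it is joined per residue;
#' positions missing from the table get probability 0 and register
#' \code{"-"}.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param ccTsv optional path of a cc-annotation TSV (see
#'   [readCcTsv()]).
#' @param species species label attached to every protein.
#' @return named list of [CCProtein-class].
#' @export
readFastaProteins <- function(path, ccTsv = NULL, species = "unknown") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  ann <- if (is.null(ccTsv)) NULL else readCcTsv(ccTsv)
  out <- lapply(seq_along(aa), function(i) {
    seqStr <- cleanSequence(as.character(aa[[i]]))
    n <- nchar(seqStr)
    prob <- rep(0, n)
    reg <- rep("-", n)
    if (!is.null(ann) && ids[i] %in% names(ann)) {
      tab <- ann[[ids[i]]]
      bad <- tab$pos < 1L | tab$pos > n
      if (any(bad))
        stop("annotation position out of range for ", ids[i])
      prob[tab$pos] <- tab$cc_prob
      reg[tab$pos] <- tab$register
    }
    CCProtein(ids[i], seqStr, prob, reg, species = species)
  })
  stats::setNames(out, ids)
}

#' Write proteins to FASTA
#'
#' @param proteins list of [CCProtein-class].
#' @param path output path.
#' @param width line width (default 60).
#' @return \code{path}, invisibly.
#' @export
writeFastaProteins <- function(proteins, path, width = 60L) {
  aa <- Biostrings::AAStringSet(vapply(proteins, as.character, ""))
  names(aa) <- vapply(proteins, function(p) p@id, "")
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read per-residue coiled-coil annotation ("cctsv v1")
#'
#' Tab-separated columns \code{protein_id}, \code{pos} (1-based),
#' \code{cc_prob}, \code{register} (\code{a}-\code{g} or \code{"-"}).
#' One row per annotated residue; rows may be sparse (missing positions
#' mean probability 0).
#'
#' @param path file path.
#' @return named list (protein id -> \code{data.frame} of \code{pos},
#'   \code{cc_prob}, \code{register}).
#' @export
readCcTsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "pos", "cc_prob", "register")
  if (!all(need %in% names(tab)))
    stop("cctsv must have columns ", paste(need, collapse = ", "))
  if (any(tab$cc_prob < 0 | tab$cc_prob > 1))
    stop("cc_prob must lie in [0, 1]")
  split(tab[c("pos", "cc_prob", "register")], tab$protein_id)
}

#' Write per-residue coiled-coil annotation ("cctsv v1")
#'
#' @param proteins list of [CCProtein-class].
#' @param path output path.
#' @param sparse drop rows with probability 0 and no register (default
#'   TRUE).
#' @return \code{path}, invisibly.
#' @export
writeCcTsv <- function(proteins, path, sparse = TRUE) {
  rows <- lapply(proteins, function(p) {
    df <- data.frame(protein_id = p@id, pos = seq_len(length(p)),
                     cc_prob = p@ccProb, register = p@register)
    if (sparse) df <- df[df$cc_prob > 0 | df$register != "-", ,
                         drop = FALSE]
    df
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gold-standard ortholog pair tables
#'
#' Two-column tab-separated files (\code{id1}, \code{id2}).
#'
#' @param path file path.
#' @return \code{data.frame} with columns \code{id1}, \code{id2}.
#' @export
readGold <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("id1", "id2") %in% names(tab)))
    stop("gold table must have columns id1, id2")
  if (any(tab$id1 == tab$id2)) stop("gold table contains self-pairs")
  tab[c("id1", "id2")]
}

#' @rdname readGold
#' @param gold pair \code{data.frame}.
#' @export
writeGold <- function(gold, path) {
  utils::write.table(gold[c("id1", "id2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write hit tables (outfmt6-like TSV)
#'
#' @param path file path.
#' @return hit \code{data.frame}.
#' @export
readHits <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname readHits
#' @param hits hit \code{data.frame} (e.g. from [allVsAll()]).
#' @param config optional [runConfig()] serialised into header comments
#'   for provenance.
#' @export
writeHits <- function(hits, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste("#", names(config), "=",
                     vapply(config, paste, "", collapse = ",")), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration with the method's default thresholds
#'
#' Central collection of all tunables with their conventional values:
#' coiled-coil cutoff 0.8, bit-score cutoff 30, coiled-coil-protein
#' content threshold 20%, gap parameters 11/1, top 50 hits per species.
#'
#' @param ... overrides of individual fields.
#' @return named list of settings.
#' @export
runConfig <- function(...) {
  cfg <- list(mode = "ccalign", matrix = "BLOSUM62", cc_cutoff = 0.8,
              bit_cutoff = 30, cc_content = 0.20, gap_open = 11L,
              gap_extend = 1L, weights_scheme = "median", bonus = 1,
              top_n = 50L, seed = 1L, log_level = "info")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname runConfig
#' @param config a config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
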