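#' @include AllClasses.R
NULL

pairKey <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")
}

#' Combine homology predictions from several methods by voting
#'
#' A link between two proteins is accepted iff at least two of the
#' supplied methods predict it. The resulting graph stores per edge the
#' number of supporting methods (\code{votes}) and the best available
#' bit score (\code{weight}).
#'
#' @param pairsByMethod named list (method -> \code{data.frame} with
#'   columns \code{id1}, \code{id2}, optional \code{species1},
#'   \code{species2}, \code{bits}); at least two methods.
#' @return a [HomologyGraph-class].
#' @examples
#' p <- function(...) data.frame(id1 = c(...)[c(TRUE, FALSE)],
#'                               id2 = c(...)[c(FALSE, TRUE)])
#' g <- combineVotes(list(a = p("x", "y"), b = p("x", "y", "y", "z"),
#'                        c = p("y", "z")))
#' igraph::ecount(homologyGraph(g))  # both pairs have 2 votes
#' @export
combineVotes <- function(pairsByMethod) {
  if (length(pairsByMethod) < 2L)
    stop("need at least two methods to vote")
  allPairs <- list()
  for (m in names(pairsByMethod)) {
    df <- pairsByMethod[[m]]
    if (nrow(df) == 0L) next
    key <- pairKey(df$id1, df$id2)
    df <- df[!duplicated(key), , drop = FALSE]
    df$..key <- key[!duplicated(key)]
    df$..method <- m
    allPairs[[m]] <- df
  }
  tab <- do.call(rbind, lapply(allPairs, function(d)
    data.frame(key = d$..key,
               bits = if ("bits" %in% names(d)) d$bits else NA_real_)))
  if (is.null(tab) || nrow(tab) == 0L) {
    return(new("HomologyGraph",
               graph = igraph::make_empty_graph(directed = FALSE)))
  }
  votes <- table(tab$key)
  kept <- names(votes)[votes >= 2L]
  bits <- vapply(kept, function(k) {
    v <- tab$bits[tab$key == k]
    if (all(is.na(v))) 1 else max(v, na.rm = TRUE)
  }, 0)
  idm <- do.call(rbind, strsplit(kept, "\r", fixed = TRUE))
  speciesOf <- do.call(rbind, lapply(allPairs, function(d) {
    sp <- if (all(c("species1", "species2") %in% names(d)))
      data.frame(id = c(d$id1, d$id2), sp = c(d$species1, d$species2))
    else data.frame(id = c(d$id1, d$id2), sp = NA_character_)
    sp
  }))
  if (length(kept) == 0L)
    return(new("HomologyGraph",
               graph = igraph::make_empty_graph(directed = FALSE)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = idm[, 1], to = idm[, 2],
               weight = bits, votes = as.integer(votes[kept])),
    directed = FALSE)
  spc <- speciesOf$sp[match(igraph::V(g)$name, speciesOf$id)]
  igraph::V(g)$species <- spc
  new("HomologyGraph", graph = g)
}

#' @rdname HomologyGraph-class
#' @export
homologyGraph <- function(x) x@graph

setMethod("homologyGroups", "HomologyGraph", function(x) {
  comp <- igraph::components(x@graph)
  split(names(comp$membership), comp$membership)
})

setMethod("show", "HomologyGraph", function(object) {
  cat("HomologyGraph:", igraph::vcount(object@graph), "proteins,",
      igraph::ecount(object@graph), "links,",
      igraph::components(object@graph)$no, "group(s)\n")
})

#' Remove spurious links via betweenness centrality
#'
#' Individual proteins can bridge unrelated groups of homologs. Within
#' each connected component, the node with the highest betweenness
#' centrality (when clearly above the component's typical level, see
#' Details) is tentatively removed; if the component then splits into
#' at least two sub-groups of two or more proteins, the split is
#' accepted and the removed protein is re-assigned to the sub-group it
#' shares most links with; otherwise the link was backed up by other
#' links and the node is restored. Newly formed sub-groups are checked
#' recursively.
#'
#' @details The candidate threshold is a centrality greater than twice
#'   the component median (and positive); components of fewer than 5
#'   nodes are left untouched. Nodes are removed one at a time, which
#'   makes the procedure deterministic.
#'
#' @param hg a [HomologyGraph-class].
#' @return a [HomologyGraph-class] with spurious bridges cut. Vertices
#'   are never dropped: accepted splits cut the bridging edges only, so
#'   the protein count is conserved.
#' @export
pruneSpurious <- function(hg) {
  g <- hg@graph
  queue <- homologyGroups(new("HomologyGraph", graph = g))
  while (length(queue)) {
    members <- queue[[1L]]
    queue <- queue[-1L]
    if (length(members) < 5L) next
    sub <- igraph::induced_subgraph(g, members)
    bt <- igraph::betweenness(sub, directed = FALSE)
    medb <- stats::median(bt)
    cand <- names(bt)[which.max(bt)]
    if (!(bt[cand] > 0 && bt[cand] > 2 * medb)) next
    rest <- igraph::delete_vertices(sub, cand)
    comp <- igraph::components(rest)
    sizes <- comp$csize
    if (comp$no >= 2L && sum(sizes >= 2L) >= 2L) {
      # accept: cut the candidate's edges except those into the
      # sub-group it shares most links with (ties -> first group by
      # smallest member id)
      nbr <- igraph::neighbors(sub, cand)$name
      grpOf <- comp$membership[nbr]
      cnt <- table(grpOf)
      grpIds <- vapply(split(names(comp$membership), comp$membership),
                       min, "")
      top <- as.integer(names(cnt)[order(-as.integer(cnt),
                                         grpIds[names(cnt)])])[1L]
      drop <- nbr[grpOf != top]
      if (length(drop)) {
        eids <- igraph::get_edge_ids(g, rbind(rep(cand, length(drop)),
                                              drop))
        g <- igraph::delete_edges(g, eids[eids > 0])
      }
      # re-examine the resulting sub-groups
      newComp <- igraph::components(
        igraph::induced_subgraph(g, members))
      queue <- c(queue, split(names(newComp$membership),
                              newComp$membership))
    }
  }
  new("HomologyGraph", graph = g)
}

#' Merge orthologous groups under a diameter cap
#'
#' Scored pairs of orthologous groups (OGs) are filtered by a score
#' threshold -- a more stringent one when the two groups contain
#' overlapping species sets, to avoid merging paralogs -- and processed
#' in decreasing score order. Two clusters are merged unless the
#' resulting cluster's group-graph diameter would exceed
#' \code{maxDiameter} edges (i.e. up to \code{maxDiameter - 1} groups
#' in between).
#'
#' @param ogPairs \code{data.frame} with columns \code{g1}, \code{g2},
#'   \code{score}.
#' @param threshold minimum score for merging.
#' @param strictThreshold minimum score when the species sets of the
#'   two groups overlap; must be >= \code{threshold}.
#' @param speciesSets named list (group id -> character vector of
#'   species present in the group).
#' @param maxDiameter maximum allowed distance (edges) between any two
#'   groups of a cluster; default 4.
#' @return named integer vector: cluster membership per group id
#'   (groups never mentioned in \code{ogPairs} are absent).
#' @export
mergeGroups <- function(ogPairs, threshold, strictThreshold,
                        speciesSets = list(), maxDiameter = 4L) {
  if (strictThreshold < threshold)
    stop("strictThreshold must be >= threshold")
  overlap <- mapply(function(a, b) {
    sa <- speciesSets[[a]]; sb <- speciesSets[[b]]
    length(intersect(sa, sb)) > 0L
  }, ogPairs$g1, ogPairs$g2)
  need <- ifelse(overlap, strictThreshold, threshold)
  keep <- ogPairs$score >= need
  df <- ogPairs[keep, , drop = FALSE]
  lo <- pmin(df$g1, df$g2); hi <- pmax(df$g1, df$g2)
  df <- df[order(-df$score, lo, hi), , drop = FALSE]
  groups <- sort(unique(c(ogPairs$g1, ogPairs$g2)))
  cluster <- stats::setNames(seq_along(groups), groups)
  edges <- list()
  for (i in seq_len(nrow(df))) {
    a <- df$g1[i]; b <- df$g2[i]
    if (cluster[a] == cluster[b]) {
      # same cluster already; the extra edge can only shrink distances
      edges[[length(edges) + 1L]] <- c(a, b)
      next
    }
    members <- names(cluster)[cluster %in% c(cluster[a], cluster[b])]
    em <- do.call(rbind, edges)
    emSub <- if (is.null(em)) NULL else
      em[em[, 1] %in% members & em[, 2] %in% members, , drop = FALSE]
    edgeDf <- rbind(data.frame(from = a, to = b),
                    if (!is.null(emSub) && nrow(emSub))
                      data.frame(from = emSub[, 1], to = emSub[, 2]))
    gg <- igraph::graph_from_data_frame(edgeDf, directed = FALSE,
                                        vertices = members)
    if (max(igraph::distances(gg)) <= maxDiameter) {
      cluster[cluster == cluster[b]] <- cluster[a]
      edges[[length(edges) + 1L]] <- c(a, b)
    }
  }
  # renumber clusters deterministically by smallest member id
  reps <- vapply(split(names(cluster), cluster), min, "")
  ord <- order(reps)
  remap <- stats::setNames(seq_along(ord), names(reps)[ord])
  stats::setNames(as.integer(remap[as.character(cluster)]),
                  names(cluster))
}
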