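#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path GMT file
#' @return named list of character vectors; each element carries its
#'   description as attribute \code{"description"}
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line needs name, description and >=1 member")
    members <- toupper(trimws(f[-(1:2)]))
    members <- unique(members[members != ""])
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Fisher-exact over-representation of gene sets in a top set
#'
#' One-sided hypergeometric tail test per gene set: with universe size N,
#' set size m (after intersecting with the universe), top-set size n and
#' overlap k, the p-value is P(X >= k) for X ~ Hypergeometric(N, m, n).
#' Over-representation only; depletion is not tested.
#'
#' @param topSet character vector of candidate molecules (subset of universe)
#' @param geneSets named list from \code{\link{readGMT}}
#' @param universe character vector, the molecule universe (defaults in the
#'   pipeline to all molecules in the database, not the genome)
#' @param adjust add a Benjamini-Hochberg column; default FALSE
#' @return \code{S4Vectors::DataFrame} sorted by p ascending with columns
#'   set, k, m, n, N, p (and p_adjust when requested)
#' @export
fisherEnrichment <- function(topSet, geneSets, universe, adjust = FALSE) {
  universe <- unique(universe)
  topSet <- unique(topSet)
  if (length(universe) == 0) stop("empty universe")
  if (length(topSet) == 0) stop("empty top set")
  if (!all(topSet %in% universe)) {
    stop("top set must be a subset of the universe: ",
         paste(utils::head(setdiff(topSet, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(topSet)
  res <- lapply(names(geneSets), function(nm) {
    members <- intersect(geneSets[[nm]], universe)
    m <- length(members)
    k <- length(intersect(members, topSet))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, m = m, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  S4Vectors::DataFrame(out)
}

#' Read an interaction edge list
#'
#' @param path two-column TSV of interacting symbols (SIF's
#'   node-relation-node layout is also accepted; the middle column is
#'   ignored). Self-loops and duplicate undirected pairs are removed.
#' @return data.frame with columns from, to
#' @export
readEdgeList <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) == 3) tab <- tab[c(1, 3)]
  if (ncol(tab) < 2) stop("edge list needs two columns")
  names(tab) <- c("from", "to")
  tab$from <- toupper(trimws(tab$from))
  tab$to <- toupper(trimws(tab$to))
  tab <- tab[tab$from != tab$to, , drop = FALSE]
  key <- ifelse(tab$from < tab$to, paste(tab$from, tab$to),
                paste(tab$to, tab$from))
  tab[!duplicated(key), , drop = FALSE]
}

# deterministic seed choice: most triangles, then highest degree, then name
.pickSeed <- function(g, candidates) {
  tri <- igraph::count_triangles(g, vids = candidates)
  deg <- igraph::degree(g, v = candidates)
  nm <- igraph::V(g)$name[candidates]
  candidates[order(-tri, -deg, nm)[1]]
}

#' Grow node-disjoint interaction networks around top molecules
#'
#' Reimplementation of the triangle-seeded subnetwork search: the seed is the
#' focus molecule participating in the most connective triangles (ties broken
#' by degree, then name). The network then grows greedily, at each step adding
#' the neighbouring molecule with the most edges into the current network,
#' preferring focus molecules over connector molecules at equal connectivity,
#' until the maximum network size is reached or no candidate connects. Nodes
#' used by one network are excluded from later ones, so the returned networks
#' are node-disjoint.
#'
#' @param focus character vector of focus molecules (the top-ranked set)
#' @param edges data.frame from \code{\link{readEdgeList}}
#' @param maxSize maximum nodes per network; default 35
#' @return list of networks, each a list with \code{nodes} (data.frame node,
#'   is_focus), \code{edges} (data.frame from, to) and \code{n_focus}
#' @export
buildNetworks <- function(focus, edges, maxSize = 35) {
  if (length(focus) == 0) stop("focus list must be non-empty")
  if (is.null(edges) || nrow(edges) == 0) {
    warning("empty edge list: no networks built")
    return(list())
  }
  g0 <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE)
  g0 <- igraph::simplify(g0)
  focus <- unique(toupper(focus))
  networks <- list()
  used <- character(0)
  repeat {
    g <- igraph::delete_vertices(g0, intersect(used, igraph::V(g0)$name))
    focusHere <- intersect(focus, igraph::V(g)$name)
    focusHere <- focusHere[igraph::degree(g, focusHere) > 0]
    if (length(focusHere) == 0) break
    seed <- .pickSeed(g, match(focusHere, igraph::V(g)$name))
    members <- igraph::V(g)$name[seed]
    repeat {
      if (length(members) >= maxSize) break
      nbr <- setdiff(unique(unlist(lapply(
        igraph::adjacent_vertices(g, members), function(x) x$name))), members)
      if (length(nbr) == 0) break
      conn <- vapply(nbr, function(v) {
        sum(igraph::V(g)$name[igraph::neighbors(g, v)] %in% members)
      }, numeric(1))
      isFocus <- nbr %in% focus
      pick <- nbr[order(-conn, -isFocus, -igraph::degree(g, nbr), nbr)[1]]
      members <- c(members, pick)
    }
    sub <- igraph::induced_subgraph(g, members)
    el <- igraph::as_data_frame(sub, what = "edges")
    networks[[length(networks) + 1]] <- list(
      nodes = data.frame(node = members, is_focus = members %in% focus,
                         stringsAsFactors = FALSE),
      edges = data.frame(from = el$from, to = el$to, stringsAsFactors = FALSE),
      n_focus = sum(members %in% focus)
    )
    used <- c(used, members)
  }
  networks
}

#' Write networks as a long table
#'
#' @param networks list from \code{\link{buildNetworks}}
#' @param path output TSV (columns network_id, node, is_focus)
#' @return invisibly, the path
#' @export
writeNetworks <- function(networks, path) {
  if (length(networks) == 0) {
    tab <- data.frame(network_id = integer(0), node = character(0),
                      is_focus = integer(0))
  } else {
    tab <- do.call(rbind, lapply(seq_along(networks), function(i) {
      data.frame(network_id = i, node = networks[[i]]$nodes$node,
                 is_focus = as.integer(networks[[i]]$nodes$is_focus),
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
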