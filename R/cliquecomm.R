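#' Enumerate all k-cliques of a network
#'
#' A k-clique is a complete subgraph on k nodes (every pair connected). For
#' the residue networks used here k = 3: a triangle of mutually interacting
#' residues.
#'
#' @param g a [rin][build_network] object or an igraph with named vertices.
#' @param k clique size, integer >= 2.
#' @return List of character vectors (sorted node names), in a deterministic
#'   lexicographic order; empty list when the graph has no k-clique.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, a - c, c - d)
#' enumerate_k_cliques(g, 3)
#' @export
enumerate_k_cliques <- function(g, k = 3L) {
  graph <- if (inherits(g, "rin")) g$graph else g
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (k > igraph::vcount(graph)) return(list())
  cl <- igraph::cliques(graph, min = k, max = k)
  cl <- lapply(cl, function(x) sort(igraph::V(graph)$name[as.integer(x)]))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

#' k-clique (clique percolation) communities
#'
#' Two k-cliques are adjacent when they share k - 1 nodes; a community is the
#' union of the node sets of a connected component of this clique-adjacency
#' relation. Communities may overlap (share nodes); nodes lying in no k-clique
#' belong to no community. For k = 3 this groups triangles that share an edge.
#'
#' @inheritParams enumerate_k_cliques
#' @param source optional identifier recorded on the result.
#' @return An object of class `clique_communities`: list with `k`,
#'   `communities` (list of sorted node-name vectors, in lexicographic order
#'   of their member lists), `n_cliques`, and `source`.
#' @examples
#' # two triangles sharing an edge percolate into one community
#' g <- igraph::make_graph(~ a - b, b - c, a - c, b - d, c - d)
#' clique_percolation(g, 3)$communities
#' @export
clique_percolation <- function(g, k = 3L, source = NULL) {
  cl <- enumerate_k_cliques(g, k)
  k <- as.integer(k)
  nc <- length(cl)
  communities <- list()
  if (nc) {
    # union-find over cliques; two k-cliques are adjacent iff they share a
    # (k-1)-subset, so cliques are grouped by their (k-1)-subset keys
    parent <- seq_len(nc)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nc)) {
      nodes <- cl[[i]]
      for (drop in seq_len(k)) {
        key <- paste(nodes[-drop], collapse = "\r")
        js <- seen[[key]]
        if (is.null(js)) {
          seen[[key]] <- i
        } else {
          ri <- find(i)
          rj <- find(js)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(nc), find, 1L)
    communities <- lapply(split(seq_len(nc), roots), function(idx) {
      sort(unique(unlist(cl[idx], use.names = FALSE)))
    })
    names(communities) <- NULL
    # full lexicographic order on member lists: deterministic even when two
    # overlapping communities share their smallest member
    communities <- communities[order(vapply(communities, paste, "",
                                            collapse = "\r"))]
  }
  structure(list(k = k, communities = communities, n_cliques = nc,
                 source = source),
            class = "clique_communities")
}

#' @export
print.clique_communities <- function(x, ...) {
  cat(sprintf("%d-clique communities: %d (from %d %d-cliques)\n",
              x$k, length(x$communities), x$n_cliques, x$k))
  for (i in seq_along(x$communities)) {
    cat(sprintf("  %d: %s\n", i,
                paste(format_residue_key_safe(x$communities[[i]]),
                      collapse = ", ")))
  }
  invisible(x)
}

# residue keys pretty-print; arbitrary node names pass through
format_residue_key_safe <- function(x) {
  ok <- grepl("^[^:]+:[0-9]+$", x)
  x[ok] <- format_residue_key(x[ok])
  x
}

#' Same-community indicator
#'
#' The indicator C_ab: 1 when some k-clique community contains both nodes
#' (including a = b when that node lies in any community), else 0. Unknown
#' nodes yield 0. Symmetric in its two node arguments.
#'
#' @param cset a [clique_percolation()] result.
#' @param a,b node identifiers.
#' @return Integer 0 or 1.
#' @export
same_community <- function(cset, a, b) {
  stopifnot(inherits(cset, "clique_communities"))
  for (comm in cset$communities) {
    if ((a %in% comm) && (b %in% comm)) return(1L)
  }
  0L
}

#' Write clique communities to JSON or TSV
#'
#' JSON: `{"k": 3, "communities": [["A:94", ...], ...]}`. TSV: one row per
#' (community, member) with columns `community_id`, `chain`, `res`.
#'
#' @param cset a `clique_communities` object.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_communities <- function(cset, path, format = c("json", "tsv")) {
  stopifnot(inherits(cset, "clique_communities"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(k = cset$k,
           communities = lapply(cset$communities, format_residue_key_safe)),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(seq_along(cset$communities), function(i) {
      keys <- cset$communities[[i]]
      sp <- strsplit(format_residue_key_safe(keys), ":", fixed = TRUE)
      data.frame(community_id = i,
                 chain = vapply(sp, `[`, "", 1),
                 res = vapply(sp, function(x) x[length(x)], ""),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      rows <- data.frame(community_id = integer(), chain = character(),
                         res = character())
    }
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
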