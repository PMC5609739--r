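#' Ordered closed adjacency lists
#'
#' Produces, for every vertex of the mapped network, its *closed*
#' adjacency list (the vertex itself plus its neighbors) sorted under a
#' total order `phi`. Closed lists make a clique's vertices mutually
#' reachable through their own lists, which is what lets the
#' intersection-size objective reach `|K|` on a clique `K`.
#'
#' Two total orders are available: `ID` sorts ascending by numeric id;
#' `FREQUENCY` sorts by decreasing indegree (the number of closed lists
#' a vertex appears in, i.e. its closed-neighborhood size), breaking
#' ties by ascending id.
#'
#' @param net a [ppi_network].
#' @param mapping a node mapping (see [build_node_ordering()]) covering the proteins of `net`; the
#'   lists are expressed in mapping ids.
#' @param phi total order, `"ID"` or `"FREQUENCY"`.
#' @return list of integer id vectors, one closed list per id (element
#'   `k` is the list contributed by the vertex with id `k`), with
#'   attributes `phi` and `n`.
#' @export
sorted_adjacency <- function(net, mapping = NULL, phi = c("ID", "FREQUENCY")) {
  phi <- match.arg(phi)
  if (!is.null(mapping)) {
    net <- remap_network(net, mapping)
  }
  n <- num_vertices(net)
  closed <- lapply(seq_len(n), function(v) c(v, net$adj[[v]]))
  if (phi == "ID") {
    lists <- lapply(closed, sort.int)
  } else {
    freq <- lengths(closed)  # indegree of id u = |closed nbhd(u)|
    lists <- lapply(closed, function(x) x[order(-freq[x], x)])
  }
  attr(lists, "phi") <- phi
  attr(lists, "n") <- n
  lists
}

#' Build a directed acyclic prefix graph from ordered adjacency lists
#'
#' Nodes are the union of all list entries; an arc joins each pair of
#' entries that are consecutive in some list. Because every list obeys
#' the same total order, arcs always point forward in that order and the
#' result is acyclic (verified by a topological sort). Each node `u`
#' carries its `vertexSet`, the set of sources whose lists contain `u`.
#'
#' @param adjlists list of integer vectors as returned by
#'   [sorted_adjacency()]; every vector must be sorted under one
#'   consistent total order.
#' @return An object of class `dapg`: list with `n_nodes`, `nodes`,
#'   `arcs` (two-column matrix, parent then child), `parents` (list of
#'   parent ids per node), `vertex_set` (list of source ids per node),
#'   `topo_order`, `phi`, and `max_depth` (filled by
#'   [compute_max_depth()]).
#' @export
build_dapg <- function(adjlists) {
  n <- attr(adjlists, "n")
  if (is.null(n)) n <- max(c(0L, unlist(adjlists)))
  len <- lengths(adjlists)
  # consecutive pairs across lists, deduplicated
  pairs <- lapply(adjlists, function(x) {
    if (length(x) >= 2L) cbind(x[-length(x)], x[-1L]) else NULL
  })
  arcs <- do.call(rbind, c(pairs, list(matrix(integer(), ncol = 2L))))
  if (nrow(arcs) > 0L) {
    arcs <- arcs[!duplicated((arcs[, 1L] - 1) * n + arcs[, 2L]), ,
                 drop = FALSE]
  }
  colnames(arcs) <- c("parent", "child")
  src <- rep.int(seq_along(adjlists), len)
  vertex_set <- split(src, factor(unlist(adjlists), levels = seq_len(n)))
  vertex_set <- unname(lapply(vertex_set, sort.int))
  parents <- split(arcs[, 1L], factor(arcs[, 2L], levels = seq_len(n)))
  parents <- unname(lapply(parents, as.integer))
  topo <- .topo_sort(n, arcs)
  if (is.null(topo)) {
    stop("adjacency lists are not consistently ordered: cycle detected")
  }
  structure(list(n_nodes = n, nodes = seq_len(n), arcs = arcs,
                 parents = parents, vertex_set = vertex_set,
                 topo_order = topo, max_depth = NULL,
                 phi = attr(adjlists, "phi")),
            class = "dapg")
}

# Kahn's algorithm; NULL if a cycle remains
.topo_sort <- function(n, arcs) {
  indeg <- tabulate(arcs[, 2L], nbins = n)
  children <- split(arcs[, 2L], factor(arcs[, 1L], levels = seq_len(n)))
  order <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    order[k] <- v
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (k < n) NULL else order
}

#' Annotate DAPG nodes with their maximum depth
#'
#' The depth of a node is the length (in nodes) of the longest path from
#' any root: roots have depth 1, every other node one more than the
#' deepest of its parents. Depths drive the `Deepest` traveler.
#'
#' @param dapg a [build_dapg()] result.
#' @return the same `dapg` with `max_depth` filled in.
#' @export
compute_max_depth <- function(dapg) {
  depth <- integer(dapg$n_nodes)
  for (u in dapg$topo_order) {
    p <- dapg$parents[[u]]
    depth[u] <- if (length(p) == 0L) 1L else max(depth[p]) + 1L
  }
  dapg$max_depth <- depth
  dapg
}

#' @export
print.dapg <- function(x, ...) {
  cat(sprintf("DAPG (phi = %s): %d nodes, %d arcs\n",
              x$phi, x$n_nodes, nrow(x$arcs)))
  invisible(x)
}

#' Build the DAPG of a network in one call
#'
#' Convenience wrapper chaining [sorted_adjacency()], [build_dapg()] and
#' [compute_max_depth()].
#'
#' @inheritParams sorted_adjacency
#' @return a depth-annotated `dapg`.
#' @export
dapg_from_network <- function(net, mapping = NULL,
                              phi = c("ID", "FREQUENCY")) {
  compute_max_depth(build_dapg(sorted_adjacency(net, mapping, phi)))
}

#' Dump a DAPG as plain-text tables
#'
#' Writes a two-column arc list and a node-attribute TSV (id,
#' vertex-set size, max depth) for debugging.
#'
#' @param dapg a depth-annotated `dapg`.
#' @param arc_path,node_path output file paths.
#' @export
write_dapg <- function(dapg, arc_path, node_path) {
  utils::write.table(dapg$arcs, arc_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  nodes <- data.frame(node = dapg$nodes,
                      vertex_set_size = lengths(dapg$vertex_set),
                      max_depth = if (is.null(dapg$max_depth)) NA_integer_
                                  else dapg$max_depth)
  utils::write.table(nodes, node_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(arc_path)
}
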