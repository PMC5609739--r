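#' Construct a PPI network object
#'
#' Builds the undirected, optionally weighted graph used throughout the
#' package. Vertices are proteins, indexed 1..n in the order of `names`;
#' edges are stored once per unordered pair with the smaller index first.
#' Self-edges and duplicated pairs (in either orientation) are collapsed,
#' keeping the first weight seen.
#'
#' @param edges two-column integer matrix (or data.frame) of vertex
#'   indices into `names`, one row per interaction.
#' @param names character vector of protein names; position defines the
#'   vertex index. Must contain no duplicates.
#' @param weights numeric vector of interaction confidences in \[0, 1\],
#'   one per row of `edges`. Ignored (forced to 1) when
#'   `graph_type = "UNONE"`.
#' @param graph_type `"UNONE"` for an unweighted network or `"USYM"` for
#'   a weighted one.
#' @return An object of class `ppi_network`: a list with elements
#'   `names`, `edges` (matrix, smaller index first), `weights`,
#'   `graph_type`, and precomputed adjacency lists `adj` (neighbor
#'   indices) and `adjw` (matching weights).
#' @export
ppi_network <- function(edges, names, weights = NULL,
                        graph_type = c("UNONE", "USYM")) {
  graph_type <- match.arg(graph_type)
  if (anyDuplicated(names)) {
    stop("protein names must be unique")
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("'edges' must have two columns")
  }
  storage.mode(edges) <- "integer"
  n <- length(names)
  if (nrow(edges) > 0L &&
      (min(edges) < 1L || max(edges) > n)) {
    stop("edge endpoints out of range")
  }
  if (is.null(weights)) {
    weights <- rep(1, nrow(edges))
  }
  if (length(weights) != nrow(edges)) {
    stop("one weight per edge required")
  }
  if (graph_type == "UNONE") {
    weights <- rep(1, nrow(edges))
  } else if (nrow(edges) > 0L &&
             (min(weights) < 0 || max(weights) > 1)) {
    stop("edge weights must lie in [0, 1]")
  }
  # canonical orientation, drop self-edges and duplicates
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  weights <- weights[keep]
  if (nrow(edges) > 0L) {
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    key <- (edges[, 1L] - 1) * n + edges[, 2L]
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    weights <- weights[first]
  }
  net <- list(names = names, edges = edges, weights = as.numeric(weights),
              graph_type = graph_type)
  net <- c(net, .build_adjacency(edges, weights, n))
  structure(net, class = "ppi_network")
}

.build_adjacency <- function(edges, weights, n) {
  adj <- vector("list", n)
  adjw <- vector("list", n)
  both_v <- c(edges[, 1L], edges[, 2L])
  both_u <- c(edges[, 2L], edges[, 1L])
  both_w <- c(weights, weights)
  fv <- factor(both_v, levels = seq_len(n))
  adj <- split(both_u, fv)
  adjw <- split(both_w, fv)
  ord <- lapply(adj, order)
  list(adj = unname(Map(function(a, o) a[o], adj, ord)),
       adjw = unname(Map(function(w, o) w[o], adjw, ord)))
}

#' Number of vertices in a PPI network
#' @param net a `ppi_network`.
#' @return integer vertex count.
#' @export
num_vertices <- function(net) length(net$names)

#' Number of edges in a PPI network
#' @param net a `ppi_network`.
#' @return integer edge count.
#' @export
num_edges <- function(net) nrow(net$edges)

#' Vertex degrees
#' @param net a `ppi_network`.
#' @return integer vector of degrees, named by protein.
#' @export
ppi_degree <- function(net) {
  d <- lengths(net$adj)
  names(d) <- net$names
  d
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network (%s): %d proteins, %d interactions\n",
              x$graph_type, num_vertices(x), num_edges(x)))
  invisible(x)
}

#' Read a PPI network from an edge-list file
#'
#' Parses a plain-text interaction file with two whitespace-separated
#' protein names per line and an optional third column holding an
#' interaction confidence in \[0, 1\]. Lines starting with `#` are
#' comments; both tabs and spaces delimit fields. Duplicate lines,
#' reversed duplicates, and self-interactions are collapsed or dropped.
#' When `graph_type = "UNONE"` any weight column is ignored (with a
#' single message) so that all interactions count equally.
#'
#' @param path path to the edge-list file.
#' @param graph_type `"UNONE"` (unweighted) or `"USYM"` (weighted).
#' @return A [ppi_network] whose vertex order is the order in which
#'   proteins are first encountered in the file.
#' @export
read_ppi <- function(path, graph_type = c("UNONE", "USYM")) {
  graph_type <- match.arg(graph_type)
  lines <- readLines(path, warn = FALSE)
  raw <- which(!grepl("^\\s*(#|$)", lines))
  tok <- strsplit(trimws(lines[raw]), "[ \t]+")
  nf <- lengths(tok)
  if (any(nf < 2L)) {
    bad <- raw[which(nf < 2L)[1L]]
    stop(sprintf("malformed interaction on line %d: need at least two fields",
                 bad))
  }
  a <- vapply(tok, `[[`, "", 1L)
  b <- vapply(tok, `[[`, "", 2L)
  w <- rep(1, length(tok))
  has_w <- nf >= 3L
  if (any(has_w)) {
    if (graph_type == "USYM") {
      wtxt <- vapply(tok[has_w], `[[`, "", 3L)
      wnum <- suppressWarnings(as.numeric(wtxt))
      if (anyNA(wnum)) {
        bad <- raw[has_w][which(is.na(wnum))[1L]]
        stop(sprintf("malformed weight on line %d", bad))
      }
      if (any(wnum < 0 | wnum > 1)) {
        bad <- raw[has_w][which(wnum < 0 | wnum > 1)[1L]]
        stop(sprintf("weight outside [0, 1] on line %d", bad))
      }
      w[has_w] <- wnum
    } else {
      message("graph type UNONE: ignoring weight column")
    }
  }
  # vertex ids in order of first appearance, scanning each line left to right
  seen <- unique(as.vector(rbind(a, b)))
  ppi_network(cbind(match(a, seen), match(b, seen)),
              names = seen, weights = w, graph_type = graph_type)
}

#' Look up the weight of an interaction
#'
#' @param net a `ppi_network`.
#' @param i,j vertex indices.
#' @return the edge weight, or `NA` if `{i, j}` is not an interaction.
#' @export
edge_weight <- function(net, i, j) {
  pos <- match(j, net$adj[[i]])
  if (is.na(pos)) NA_real_ else net$adjw[[i]][pos]
}

#' Relabel a network so vertex indices equal mapped numeric ids
#'
#' The mining stages work on numeric ids assigned by a node ordering.
#' This helper permutes a network so that vertex `i` is the protein with
#' id `i` under `mapping`, letting DAPG node labels double as vertex
#' indices.
#'
#' @param net a `ppi_network`.
#' @param mapping a node mapping (see [build_node_ordering()]) covering exactly the proteins of `net`.
#' @return a `ppi_network` with vertices in mapping-id order.
#' @export
remap_network <- function(net, mapping) {
  ids <- match(net$names, mapping$order)
  if (anyNA(ids) || length(mapping$order) != num_vertices(net)) {
    stop("mapping must be a permutation of the network's proteins")
  }
  ppi_network(cbind(ids[net$edges[, 1L]], ids[net$edges[, 2L]]),
              names = mapping$order, weights = net$weights,
              graph_type = net$graph_type)
}
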