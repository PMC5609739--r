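#' Prediction configuration
#'
#' Collects everything needed to turn a raw network into predicted
#' complexes: the node ordering scheme, the mining configuration, the
#' minimum complex size, and the grouping mode applied to candidates.
#'
#' @param min_size minimum number of proteins in a candidate complex
#'   (default 3, the value used throughout the benchmark runs).
#' @param grouping `"NONE"` (candidates are the predictions) or
#'   `"UNION"` (merge candidate pairs whose overlap score exceeds
#'   `union_threshold`).
#' @param union_threshold overlap-score threshold for `UNION` grouping,
#'   in (0, 1\]; default 0.8.
#' @param mining a [mining_config()].
#' @param ordering node ordering scheme (see [build_node_ordering()]).
#' @param seed integer seed for the `random` ordering.
#' @return a `predict_config` list.
#' @export
predict_config <- function(min_size = 3L,
                           grouping = c("NONE", "UNION"),
                           union_threshold = 0.8,
                           mining = mining_config(),
                           ordering = "first",
                           seed = NULL) {
  grouping <- match.arg(grouping)
  if (min_size < 1L) stop("min_size must be at least 1")
  if (union_threshold <= 0 || union_threshold > 1) {
    stop("union_threshold must lie in (0, 1]")
  }
  structure(list(min_size = as.integer(min_size), grouping = grouping,
                 union_threshold = union_threshold, mining = mining,
                 ordering = ordering, seed = seed),
            class = "predict_config")
}

#' Candidate complexes from maximal dense subgraphs
#'
#' Each dense subgraph becomes the candidate complex `S ∪ C`, translated
#' back to protein names, and is kept when it has at least `min_size`
#' members. Duplicate member sets are collapsed.
#'
#' @param dsgs list of `dense_subgraph` objects (maximality-filtered).
#' @param min_size minimum complex size.
#' @param mapping the node mapping (see [build_node_ordering()]) used to build the DAPG, for
#'   translating ids back to protein names.
#' @return a [complex_set].
#' @export
candidates_from_dsgs <- function(dsgs, min_size, mapping) {
  members <- lapply(dsgs, function(d) mapping$order[union(d$S, d$C)])
  members <- members[lengths(members) >= min_size]
  if (length(members) == 0L) {
    return(structure(list(complexes = list(), labels = NULL),
                     class = "complex_set"))
  }
  complex_set(members)
}

#' Merge highly overlapping complexes by set union
#'
#' Builds a graph over complexes with an edge wherever the overlap score
#' strictly exceeds `threshold`, and replaces each connected component
#' by the union of its members (so merging is transitive and
#' order-independent in a single pass).
#'
#' @param cs a [complex_set].
#' @param threshold overlap-score threshold in (0, 1\].
#' @return the grouped [complex_set].
#' @export
group_union <- function(cs, threshold = 0.8) {
  k <- length(cs$complexes)
  if (k <= 1L) return(cs)
  pairs <- utils::combn(k, 2L)
  os <- apply(pairs, 2L, function(p) {
    overlap_score(cs$complexes[[p[1L]]], cs$complexes[[p[2L]]])
  })
  hit <- os > threshold
  if (!any(hit)) return(cs)
  g <- igraph::graph_from_edgelist(t(pairs[, hit, drop = FALSE]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  merged <- lapply(split(seq_len(k), comp), function(idx) {
    unique(unlist(cs$complexes[idx]))
  })
  complex_set(merged)
}

#' Predict protein complexes from a PPI network
#'
#' Runs the whole pipeline: node ordering, sorted closed adjacency
#' lists, DAPG construction and depth annotation, greedy dense-subgraph
#' mining with maximality filtering, size filtering, and optional union
#' grouping. Deterministic for a fixed configuration (including seed).
#'
#' @param net a [ppi_network].
#' @param config a [predict_config()].
#' @param mapping optional node mapping (see [build_node_ordering()]) overriding
#'   `config$ordering` (e.g. one read with [read_node_mapping()]).
#' @return a [complex_set] of predicted complexes.
#' @export
predict_complexes <- function(net, config = predict_config(),
                              mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- build_node_ordering(net, config$ordering, config$seed)
  }
  mapped <- remap_network(net, mapping)
  dapg <- dapg_from_network(mapped, phi = config$mining$phi)
  dsgs <- mine_all(dapg, config$mining, mapped)
  cands <- candidates_from_dsgs(dsgs, config$min_size, mapping)
  if (config$grouping == "UNION") {
    cands <- group_union(cands, config$union_threshold)
  }
  cands
}
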