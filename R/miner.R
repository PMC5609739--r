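#' Mining configuration
#'
#' Bundles the three knobs of the dense-subgraph search: the inverse
#' traveler that picks which parent to visit while walking a DAPG node
#' toward a root, the objective that scores candidate subgraphs, and the
#' total order used to sort adjacency lists.
#'
#' Objectives:
#' * `UNONE` — intersection size `|S ∩ C|` (the unweighted default);
#' * `WDEGREE` — weighted degree density, sum of weights over the edges
#'   of `S × C` divided by `|S ∪ C|`;
#' * `WEDGE` — weighted edge density, twice that sum divided by
#'   `|S ∪ C| (|S ∪ C| − 1)`;
#' * `FWDEGREE` / `FWEDGE` — the same two densities computed over *all*
#'   network edges induced by `S ∪ C`, not only the bipartite ones.
#'
#' @param traveler `"deepest"` (follow a parent of maximal depth) or
#'   `"sharing"` (follow the parent sharing the largest vertex set).
#' @param objective one of `"UNONE"`, `"WDEGREE"`, `"WEDGE"`,
#'   `"FWDEGREE"`, `"FWEDGE"`.
#' @param phi adjacency-list total order, `"ID"` or `"FREQUENCY"`.
#' @return a `mining_config` list.
#' @export
mining_config <- function(traveler = c("deepest", "sharing"),
                          objective = c("UNONE", "WDEGREE", "WEDGE",
                                        "FWDEGREE", "FWEDGE"),
                          phi = c("ID", "FREQUENCY")) {
  structure(list(traveler = match.arg(traveler),
                 objective = match.arg(objective),
                 phi = match.arg(phi)),
            class = "mining_config")
}

#' Score a dense subgraph under an objective function
#'
#' `S` and `C` are vertex ids of the (mapped) network. The edge set
#' `E(S × C)` is the set of unordered pairs `{s, c}` with `s` in `S`,
#' `c` in `C`, `s != c`, that are network edges, each counted once; the
#' full variants instead use every network edge with both endpoints in
#' `S ∪ C`. Density denominators smaller than 2 yield a score of 0.
#'
#' @param S,C integer id vectors (both nonempty).
#' @param objective objective name (see [mining_config()]).
#' @param net the [ppi_network] in mapping-id space.
#' @return a single numeric score.
#' @export
objective_score <- function(S, C, objective, net) {
  if (length(S) == 0L || length(C) == 0L) {
    stop("S and C must be nonempty")
  }
  if (objective == "UNONE") {
    return(length(intersect(S, C)))
  }
  U <- union(S, C)
  nu <- length(U)
  wsum <- if (objective %in% c("FWDEGREE", "FWEDGE")) {
    .induced_weight_sum(U, net)
  } else {
    .bipartite_weight_sum(S, C, net)
  }
  switch(objective,
         WDEGREE = ,
         FWDEGREE = wsum / nu,
         WEDGE = ,
         FWEDGE = if (nu < 2L) 0 else 2 * wsum / (nu * (nu - 1)))
}

# sum of weights over unordered pairs {s, c}, s in S, c in C, that are edges
.bipartite_weight_sum <- function(S, C, net) {
  n <- num_vertices(net)
  keys <- ws <- vector("list", length(C))
  for (k in seq_along(C)) {
    cc <- C[k]
    nb <- net$adj[[cc]]
    sel <- nb %in% S
    if (!any(sel)) next
    p <- nb[sel]
    keys[[k]] <- (pmin(p, cc) - 1) * n + pmax(p, cc)
    ws[[k]] <- net$adjw[[cc]][sel]
  }
  key <- unlist(keys)
  if (is.null(key)) return(0)
  sum(unlist(ws)[!duplicated(key)])
}

# sum of weights over network edges with both endpoints in U
.induced_weight_sum <- function(U, net) {
  n <- num_vertices(net)
  keys <- ws <- vector("list", length(U))
  for (k in seq_along(U)) {
    v <- U[k]
    nb <- net$adj[[v]]
    sel <- nb %in% U & nb > v  # each edge once
    if (!any(sel)) next
    keys[[k]] <- TRUE
    ws[[k]] <- net$adjw[[v]][sel]
  }
  sum(unlist(ws))
}

#' Step an inverse traveler one node toward a root
#'
#' @param dapg a depth-annotated [dapg_from_network()] result.
#' @param u current node id.
#' @param traveler `"deepest"` or `"sharing"`.
#' @return the chosen parent id, or `NULL` when `u` is a root. Ties are
#'   broken toward the smallest id.
#' @export
traveler_next <- function(dapg, u, traveler = c("deepest", "sharing")) {
  traveler <- match.arg(traveler)
  p <- dapg$parents[[u]]
  if (length(p) == 0L) return(NULL)
  if (traveler == "deepest") {
    if (is.null(dapg$max_depth)) {
      stop("run compute_max_depth() before using the deepest traveler")
    }
    cand <- p[dapg$max_depth[p] == max(dapg$max_depth[p])]
  } else {
    vs_u <- dapg$vertex_set[[u]]
    share <- vapply(p, function(q) length(intersect(vs_u,
                                                    dapg$vertex_set[[q]])),
                    0L)
    cand <- p[share == max(share)]
  }
  min(cand)
}

#' Mine one dense subgraph starting from a DAPG node
#'
#' Starts from the seed state `S = vertexSet(u)`, `C = {u}` and walks
#' toward a root along the path fixed by the traveler. At each visited
#' node `p` the tentative refinement `S' = S ∩ vertexSet(p)`,
#' `C' = C ∪ {p}` is accepted only when `S'` is nonempty and the
#' objective strictly improves; rejected nodes do not stop the walk.
#' Since acceptance requires strict improvement, the state held when a
#' root is reached is the best-scoring snapshot seen.
#'
#' @param dapg a depth-annotated `dapg`.
#' @param u starting node id.
#' @param cfg a [mining_config()].
#' @param net the [ppi_network] in mapping-id space.
#' @return An object of class `dense_subgraph`: list with sorted id
#'   vectors `S` and `C`, the objective `score`, the `seed_node`, and
#'   `n_accepted`, the number of walk nodes that joined `C`.
#' @export
mine_from_node <- function(dapg, u, cfg, net) {
  S <- dapg$vertex_set[[u]]
  C <- u
  score <- objective_score(S, C, cfg$objective, net)
  accepted <- 0L
  pos <- u
  repeat {
    p <- traveler_next(dapg, pos, cfg$traveler)
    if (is.null(p)) break
    Sp <- intersect(S, dapg$vertex_set[[p]])
    if (length(Sp) > 0L) {
      Cp <- c(C, p)
      sc <- objective_score(Sp, Cp, cfg$objective, net)
      if (sc > score) {
        S <- Sp
        C <- Cp
        score <- sc
        accepted <- accepted + 1L
      }
    }
    pos <- p
  }
  structure(list(S = sort.int(S), C = sort.int(C), score = score,
                 seed_node = u, n_accepted = accepted),
            class = "dense_subgraph")
}

#' @export
print.dense_subgraph <- function(x, ...) {
  cat(sprintf("DSG from node %d: |S| = %d, |C| = %d, score %.4g\n",
              x$seed_node, length(x$S), length(x$C), x$score))
  invisible(x)
}

#' Mine dense subgraphs from every DAPG node
#'
#' Runs [mine_from_node()] from each node (one candidate per node), then
#' discards *unexpanded stars* — seeds whose walk accepted nothing, so
#' that `C` is still the single start node while `S` is its whole closed
#' neighborhood. Such a candidate is just a vertex neighborhood, not a
#' mined structure, and its large vertex set would otherwise absorb
#' genuine cliques during maximality filtering (isolated vertices, whose
#' neighborhood is only themselves, are kept). Finally
#' [filter_maximal()] retains only subgraphs whose vertex set is not
#' contained in another's.
#'
#' @param dapg a depth-annotated `dapg`.
#' @param cfg a [mining_config()].
#' @param net the [ppi_network] in mapping-id space.
#' @param drop_unexpanded keep the star-pruning step (default `TRUE`);
#'   `FALSE` retains all per-node candidates for inspection.
#' @return list of maximal `dense_subgraph` objects.
#' @export
mine_all <- function(dapg, cfg, net, drop_unexpanded = TRUE) {
  cands <- lapply(dapg$nodes, mine_from_node, dapg = dapg, cfg = cfg,
                  net = net)
  if (drop_unexpanded) {
    keep <- vapply(cands, function(d) {
      d$n_accepted > 0L || length(d$S) == 1L
    }, NA)
    cands <- cands[keep]
  }
  filter_maximal(cands)
}

#' Keep only maximal dense subgraphs
#'
#' A subgraph is removed when its vertex set `S ∪ C` is a subset of a
#' retained subgraph's vertex set. Among subgraphs with identical vertex
#' sets one survivor is kept: highest score, then smallest seed node.
#'
#' @param dsgs list of `dense_subgraph` objects.
#' @return the maximal sublist, ordered by decreasing vertex-set size.
#' @export
filter_maximal <- function(dsgs) {
  if (length(dsgs) == 0L) return(dsgs)
  unions <- lapply(dsgs, function(d) union(d$S, d$C))  # already sorted inputs
  unions <- lapply(unions, sort.int)
  sizes <- lengths(unions)
  scores <- vapply(dsgs, `[[`, 0, "score")
  seeds <- vapply(dsgs, `[[`, 0L, "seed_node")
  ord <- order(-sizes, -scores, seeds)
  dsgs <- dsgs[ord]
  unions <- unions[ord]
  sizes <- sizes[ord]
  key <- vapply(unions, paste, "", collapse = ",")
  first <- !duplicated(key)
  dsgs <- dsgs[first]
  unions <- unions[first]
  sizes <- sizes[first]
  kept <- list()
  kept_unions <- list()
  for (i in seq_along(dsgs)) {
    contained <- FALSE
    for (ku in kept_unions) {
      if (all(unions[[i]] %in% ku)) {
        contained <- TRUE
        break
      }
    }
    if (!contained) {
      kept[[length(kept) + 1L]] <- dsgs[[i]]
      kept_unions[[length(kept_unions) + 1L]] <- unions[[i]]
    }
  }
  kept
}

#' Check that a dense subgraph is valid against a network
#'
#' Verifies `S × C ⊆ E` after removing self-pairs: every pair `(s, c)`
#' with `s != c` must be a network edge.
#'
#' @param dsg a `dense_subgraph`.
#' @param net the [ppi_network] in mapping-id space.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_dsg <- function(dsg, net) {
  for (cc in dsg$C) {
    s <- setdiff(dsg$S, cc)
    if (!all(s %in% net$adj[[cc]])) return(FALSE)
  }
  length(dsg$S) > 0L && length(dsg$C) > 0L
}
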