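#' Specification for a synthetic planted-complex network
#'
#' Describes a network built from planted complexes (cliques, optionally
#' with one edge removed to mimic near-clique complexes observed in real
#' interactomes), chained overlaps through shared proteins
#' (multifunctional proteins belong to consecutive complexes), plus
#' Erdos-Renyi background noise.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer pair `(min, max)` of complex sizes;
#'   `min >= 3`.
#' @param overlap_fraction probability in \[0, 1\] that a complex shares
#'   one protein with the previously planted complex.
#' @param background_vertices number of extra proteins outside every
#'   complex.
#' @param background_edge_prob probability of a noise edge between any
#'   pair of vertices not already linked by a planted edge.
#' @param weight_noise when positive, edge weights are drawn uniformly
#'   from `[1 - weight_noise, 1]` and the network is weighted (`USYM`);
#'   0 gives an unweighted network.
#' @param drop_edge_fraction fraction of planted complexes (of size at
#'   least 4) that lose one random internal edge.
#' @param seed integer seed making the construction deterministic.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_complexes = 5L, size_range = c(3L, 6L),
                           overlap_fraction = 0, background_vertices = 0L,
                           background_edge_prob = 0, weight_noise = 0,
                           drop_edge_fraction = 0, seed = 1L) {
  if (size_range[1L] < 3L) stop("minimum complex size is 3")
  if (size_range[2L] < size_range[1L]) stop("invalid size range")
  probs <- c(overlap_fraction, background_edge_prob, drop_edge_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (weight_noise < 0 || weight_noise > 1) {
    stop("weight_noise must lie in [0, 1]")
  }
  if (n_complexes < 1L) stop("need at least one complex")
  if (overlap_fraction > 0 && size_range[1L] < 3L) {
    stop("overlapping complexes need size at least 3")
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 overlap_fraction = overlap_fraction,
                 background_vertices = as.integer(background_vertices),
                 background_edge_prob = background_edge_prob,
                 weight_noise = weight_noise,
                 drop_edge_fraction = drop_edge_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a network with planted ground-truth complexes
#'
#' Complexes are planted sequentially as cliques; with probability
#' `overlap_fraction` a complex reuses one protein of its predecessor.
#' Background vertices and Erdos-Renyi noise edges are then added, and
#' optionally one internal edge per selected complex is removed. The
#' returned ground truth records the planted member sets.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `network` (a [ppi_network]) and `truth`
#'   (a [complex_set]).
#' @export
planted_network <- function(spec) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  size_pool <- seq(spec$size_range[1L], spec$size_range[2L])
  sizes <- size_pool[sample.int(length(size_pool), spec$n_complexes,
                                replace = TRUE)]
  members <- vector("list", spec$n_complexes)
  next_id <- 1L
  for (i in seq_len(spec$n_complexes)) {
    shared <- character()
    if (i > 1L && stats::runif(1) < spec$overlap_fraction) {
      shared <- sample(members[[i - 1L]], 1L)
    }
    fresh <- sprintf("P%04d", seq.int(next_id,
                                      length.out = sizes[i] - length(shared)))
    next_id <- next_id + length(fresh)
    members[[i]] <- c(shared, fresh)
  }
  if (spec$background_vertices > 0L) {
    bg <- sprintf("B%04d", seq_len(spec$background_vertices))
  } else {
    bg <- character()
  }
  all_names <- unique(c(unlist(members), bg))
  idx <- function(x) match(x, all_names)
  clique_edges <- function(m) {
    if (length(m) < 2L) return(NULL)
    t(utils::combn(idx(m), 2L))
  }
  edges <- do.call(rbind, lapply(members, clique_edges))
  # one random internal edge removed from selected larger complexes
  if (spec$drop_edge_fraction > 0) {
    droppable <- which(sizes >= 4L)
    n_drop <- floor(spec$drop_edge_fraction * length(droppable))
    for (i in utils::head(droppable, n_drop)) {
      within <- idx(members[[i]])
      cand <- which(edges[, 1L] %in% within & edges[, 2L] %in% within)
      edges <- edges[-sample(cand, 1L), , drop = FALSE]
    }
  }
  key <- (pmin(edges[, 1L], edges[, 2L]) - 1) * length(all_names) +
    pmax(edges[, 1L], edges[, 2L])
  edges <- edges[!duplicated(key), , drop = FALSE]
  key <- unique(key)
  if (spec$background_edge_prob > 0 && length(all_names) >= 2L) {
    allp <- utils::combn(length(all_names), 2L)
    pkey <- (allp[1L, ] - 1) * length(all_names) + allp[2L, ]
    free <- which(!(pkey %in% key))
    add <- free[stats::runif(length(free)) < spec$background_edge_prob]
    if (length(add) > 0L) {
      edges <- rbind(edges, t(allp[, add, drop = FALSE]))
    }
  }
  weighted <- spec$weight_noise > 0
  weights <- if (weighted) {
    stats::runif(nrow(edges), 1 - spec$weight_noise, 1)
  } else NULL
  net <- ppi_network(edges, all_names, weights,
                     graph_type = if (weighted) "USYM" else "UNONE")
  list(network = net, truth = complex_set(members))
}

#' Add random spurious interactions to a network
#'
#' Inserts `floor(fraction * |E|)` uniformly sampled edges between
#' vertex pairs that are not yet interacting (and are not self-pairs),
#' leaving every original edge untouched. New edges get weight 1 on
#' unweighted networks and a uniform weight in \[0, 1\] on weighted
#' ones. Used to probe robustness of the predictions to noise.
#'
#' @param net a [ppi_network].
#' @param fraction nonnegative fraction of the current edge count.
#' @param seed integer seed.
#' @return the augmented [ppi_network].
#' @export
add_random_edges <- function(net, fraction, seed = 1L) {
  if (fraction < 0) stop("fraction must be nonnegative")
  n <- num_vertices(net)
  m_new <- floor(fraction * num_edges(net))
  if (m_new == 0L) return(net)
  total_pairs <- n * (n - 1) / 2
  if (num_edges(net) + m_new > total_pairs) {
    stop("network too dense to place the requested random edges")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  existing <- (net$edges[, 1L] - 1) * n + net$edges[, 2L]
  chosen <- integer(0)
  new_edges <- matrix(integer(), ncol = 2L)
  while (nrow(new_edges) < m_new) {
    need <- m_new - nrow(new_edges)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(n, 2L * need, replace = TRUE)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    ok <- lo != hi
    key <- (lo - 1) * n + hi
    ok <- ok & !(key %in% existing) & !(key %in% chosen) & !duplicated(key)
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    chosen <- c(chosen, key[take])
    new_edges <- rbind(new_edges, cbind(lo[take], hi[take]))
  }
  w_new <- if (net$graph_type == "USYM") {
    stats::runif(m_new)
  } else rep(1, m_new)
  ppi_network(rbind(net$edges, new_edges), net$names,
              c(net$weights, w_new), net$graph_type)
}

#' The seven-protein worked-example network
#'
#' A 7-vertex, 12-edge toy network whose maximal cliques are
#' `{1, 2, 3}`, `{3, 4, 5, 6}` and `{4, 5, 6, 7}`, together with that
#' clique set as ground truth. Small enough to trace the whole mining
#' walk by hand, yet rich enough to exercise overlapping complexes.
#'
#' @return list with `network` (a [ppi_network]) and `truth` (a
#'   [complex_set]).
#' @export
fig1_fixture <- function() {
  cliques <- list(c(1L, 2L, 3L), c(3L, 4L, 5L, 6L), c(4L, 5L, 6L, 7L))
  edges <- do.call(rbind, lapply(cliques, function(k) t(utils::combn(k, 2L))))
  net <- ppi_network(edges, names = as.character(1:7))
  list(network = net,
       truth = complex_set(lapply(cliques, as.character)))
}
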