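# Shared fixtures and independent oracles for the test suite.

# seeded Erdos-Renyi network over n named proteins
random_network <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  nm <- sprintf("V%02d", seq_len(n))
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  w <- if (weighted) runif(nrow(edges)) else NULL
  ppi_network(edges, nm, w, graph_type = if (weighted) "USYM" else "UNONE")
}

# a ppi_network as an igraph object (oracle side only)
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = num_vertices(net), directed = FALSE)
  igraph::add_edges(g, t(net$edges))
}

# maximal cliques of size >= min_size, as sorted member-name sets
oracle_cliques <- function(net, min_size = 3L) {
  cl <- igraph::max_cliques(as_igraph(net), min = min_size)
  lapply(cl, function(v) sort(net$names[as.integer(v)], method = "radix"))
}

set_of_sets <- function(complexes) {
  sort(vapply(complexes, function(x) paste(sort(x), collapse = ","), ""))
}

# exact MMR by exhaustive search over one-to-one assignments
brute_mmr <- function(pred, ref, min_os = 0.2) {
  np <- length(pred$complexes)
  nr <- length(ref$complexes)
  os <- matrix(0, nr, np)
  for (i in seq_len(nr)) {
    for (j in seq_len(np)) {
      s <- overlap_score(pred$complexes[[j]], ref$complexes[[i]])
      if (s >= min_os) os[i, j] <- s
    }
  }
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > nr) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(i + 1L, used, acc)  # leave reference i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && os[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + os[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0)
  best / nr
}

# random complex set: k complexes over a protein universe
random_complexes <- function(k, universe, size_range = c(2L, 5L)) {
  complex_set(lapply(seq_len(k), function(i) {
    sample(universe, sample(seq(size_range[1L], size_range[2L]), 1L))
  }))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
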