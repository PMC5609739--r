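#' Node ordering: assign numeric ids to proteins
#'
#' Maps every protein of a network to a numeric id (its position in the
#' returned permutation). Six schemes are supported:
#'
#' * `first` — the order in which proteins were read from the input file;
#' * `lexicographic` — protein names sorted (C-locale radix sort);
#' * `degree` — decreasing network degree, ties by name;
#' * `random` — a seeded shuffle;
#' * `bfs` / `dfs` — breadth- or depth-first traversal order. Traversals
#'   start at the highest-degree vertex (ties by name), expand neighbors
#'   in lexicographic name order, and restart from the next unvisited
#'   highest-degree vertex when a component is exhausted.
#'
#' @param net a [ppi_network].
#' @param scheme one of `"first"`, `"lexicographic"`, `"degree"`,
#'   `"random"`, `"bfs"`, `"dfs"`.
#' @param seed integer seed; required for (and only used by) the
#'   `random` scheme.
#' @return A `node_mapping`: list with `scheme`, `order` (protein names
#'   in id order, so `order[k]` has id `k`), and `seed`.
#' @export
build_node_ordering <- function(net,
                                scheme = c("first", "lexicographic",
                                           "degree", "random",
                                           "bfs", "dfs"),
                                seed = NULL) {
  scheme <- match.arg(scheme)
  if (num_vertices(net) == 0L) {
    stop("network has no vertices")
  }
  nm <- net$names
  ord <- switch(scheme,
    first = nm,
    lexicographic = sort(nm, method = "radix"),
    degree = {
      d <- lengths(net$adj)
      nm[order(-d, nm, method = "radix")]
    },
    random = {
      if (is.null(seed)) stop("the random scheme requires a seed")
      old <- .save_rng()
      on.exit(.restore_rng(old))
      set.seed(as.integer(seed))
      sample(nm)
    },
    bfs = .traversal_order(net, breadth = TRUE),
    dfs = .traversal_order(net, breadth = FALSE)
  )
  structure(list(scheme = scheme, order = ord,
                 seed = if (scheme == "random") as.integer(seed) else NULL),
            class = "node_mapping")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic BFS/DFS over the whole network (restarting per component).
.traversal_order <- function(net, breadth) {
  n <- num_vertices(net)
  nm <- net$names
  d <- lengths(net$adj)
  # vertices by decreasing degree, ties by name: restart order
  restart <- order(-d, nm, method = "radix")
  # neighbors pre-sorted lexicographically by name
  nbrs <- lapply(net$adj, function(a) a[order(nm[a], method = "radix")])
  visited <- logical(n)
  out <- integer(n)
  k <- 0L
  for (s in restart) {
    if (visited[s]) next
    if (breadth) {
      queue <- s
      visited[s] <- TRUE
      while (length(queue) > 0L) {
        v <- queue[1L]
        queue <- queue[-1L]
        k <- k + 1L
        out[k] <- v
        fresh <- nbrs[[v]][!visited[nbrs[[v]]]]
        visited[fresh] <- TRUE
        queue <- c(queue, fresh)
      }
    } else {
      stack <- s
      while (length(stack) > 0L) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (visited[v]) next
        visited[v] <- TRUE
        k <- k + 1L
        out[k] <- v
        fresh <- nbrs[[v]][!visited[nbrs[[v]]]]
        # push reversed so the lexicographically smallest is expanded first
        stack <- c(stack, rev(fresh))
      }
    }
  }
  nm[out]
}

#' @export
print.node_mapping <- function(x, ...) {
  cat(sprintf("node mapping (%s): %d proteins\n", x$scheme, length(x$order)))
  invisible(x)
}

#' Numeric ids of proteins under a mapping
#'
#' @param mapping a `node_mapping`.
#' @param names protein names to translate.
#' @return integer ids (positions in `mapping$order`).
#' @export
mapping_ids <- function(mapping, names) {
  match(names, mapping$order)
}

#' Read / write a protein-to-id mapping file
#'
#' The mapping file dialect is two whitespace-separated columns,
#' `protein_name numeric_id`, so externally produced orderings can be
#' injected into the pipeline. Ids may be any distinct integers; ranks
#' define the permutation.
#'
#' @param path file path.
#' @return `read_node_mapping` returns a `node_mapping` with scheme
#'   `"file"`.
#' @export
read_node_mapping <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "id"),
                           colClasses = c("character", "integer"))
  if (anyDuplicated(tab$name) || anyDuplicated(tab$id)) {
    stop("mapping file must pair distinct proteins with distinct ids")
  }
  structure(list(scheme = "file",
                 order = tab$name[order(tab$id)],
                 seed = NULL),
            class = "node_mapping")
}

#' @rdname read_node_mapping
#' @param mapping a `node_mapping` to serialize.
#' @export
write_node_mapping <- function(mapping, path) {
  writeLines(paste(mapping$order, seq_along(mapping$order)), path)
  invisible(path)
}
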