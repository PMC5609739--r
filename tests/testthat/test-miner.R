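fig1_dapg <- function(phi = "ID") {
  fx <- fig1_fixture()
  mapping <- build_node_ordering(fx$network, "first")
  net <- remap_network(fx$network, mapping)
  list(dapg = dapg_from_network(net, phi = phi), net = net)
}

test_that("objective functions match their closed forms", {
  tri <- ppi_network(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                     as.character(1:3))
  expect_equal(objective_score(1:3, 1:3, "UNONE", tri), 3)
  expect_equal(objective_score(1:3, 1:3, "WDEGREE", tri), 1)
  expect_equal(objective_score(1:3, 1:3, "WEDGE", tri), 1)
  # S = {1}, C = {2,3}: two bipartite edges, but the induced triangle has 3
  expect_equal(objective_score(1L, 2:3, "WDEGREE", tri), 2 / 3)
  expect_equal(objective_score(1L, 2:3, "FWDEGREE", tri), 1)
  expect_equal(objective_score(1L, 2:3, "WEDGE", tri), 2 * 2 / (3 * 2))
  expect_equal(objective_score(1L, 2:3, "FWEDGE", tri), 1)

  # complete bipartite K2,2 with all weights 0.5
  k22 <- ppi_network(rbind(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L)),
                     as.character(1:4), weights = rep(0.5, 4),
                     graph_type = "USYM")
  expect_equal(objective_score(1:2, 3:4, "WDEGREE", k22), 0.5)
  expect_equal(objective_score(1:2, 3:4, "WEDGE", k22), 1 / 3)

  # degenerate density denominator
  lone <- ppi_network(matrix(integer(), ncol = 2), "1")
  expect_equal(objective_score(1L, 1L, "WEDGE", lone), 0)
  expect_error(objective_score(integer(), 1L, "UNONE", lone), "nonempty")
})

test_that("travelers follow depth or shared vertex sets and stop at roots", {
  chain <- list(1:3)
  attr(chain, "n") <- 3L
  d <- compute_max_depth(build_dapg(chain))
  expect_equal(traveler_next(d, 3L, "deepest"), 2L)
  expect_null(traveler_next(d, 1L, "deepest"))
  expect_null(traveler_next(d, 1L, "sharing"))

  # node 3 has parents 1 and 2; vertexSet overlap decides for sharing:
  # vertexSet(3) = {1,2,3,4}, vertexSet(1) = {1,3}, vertexSet(2) = {1,2,4}
  lists <- list(c(1L, 2L, 3L), c(2L, 3L), c(1L, 3L), c(2L, 3L, 6L))
  attr(lists, "n") <- 6L
  ds <- compute_max_depth(build_dapg(lists))
  expect_equal(traveler_next(ds, 3L, "sharing"), 2L)
  # deepest ties broken toward the smallest id
  expect_equal(traveler_next(ds, 3L, "deepest"), 2L)
})

test_that("mining walks reproduce the worked-example hand traces", {
  f <- fig1_dapg("ID")
  cfg <- mining_config("deepest", "UNONE", "ID")

  d7 <- mine_from_node(f$dapg, 7L, cfg, f$net)
  expect_equal(d7$S, 4:7)
  expect_equal(d7$C, 4:7)
  expect_equal(d7$score, 4)

  d6 <- mine_from_node(f$dapg, 6L, cfg, f$net)
  expect_equal(union(d6$S, d6$C), 3:6)
  expect_equal(d6$score, 4)

  # the root's walk cannot move: bare seed state
  d1 <- mine_from_node(f$dapg, 1L, cfg, f$net)
  expect_equal(d1$S, 1:3)
  expect_equal(d1$C, 1L)
  expect_equal(d1$n_accepted, 0L)
})

test_that("full mining recovers the three overlapping cliques", {
  for (phi in c("ID", "FREQUENCY")) {
    f <- fig1_dapg(phi)
    cfg <- mining_config("deepest", "UNONE", phi)
    dsgs <- mine_all(f$dapg, cfg, f$net)
    unions <- lapply(dsgs, function(d) union(d$S, d$C))
    expect_equal(set_of_sets(unions),
                 set_of_sets(list(1:3, 3:6, 4:7)))
  }
})

test_that("a triangle collapses to a single dense subgraph", {
  tri <- ppi_network(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                     as.character(1:3))
  d <- dapg_from_network(tri, build_node_ordering(tri, "first"), "ID")
  dsgs <- mine_all(d, mining_config("deepest", "UNONE", "ID"), tri)
  expect_equal(length(dsgs), 1L)
  expect_equal(sort(union(dsgs[[1L]]$S, dsgs[[1L]]$C)), 1:3)
})

test_that("an edgeless graph yields only singleton subgraphs", {
  iso <- ppi_network(matrix(integer(), ncol = 2), as.character(1:4))
  d <- dapg_from_network(iso, build_node_ordering(iso, "first"), "ID")
  dsgs <- mine_all(d, mining_config("deepest", "UNONE", "ID"), iso)
  expect_equal(length(dsgs), 4L)
  expect_true(all(vapply(dsgs, function(x) length(union(x$S, x$C)), 0L) == 1L))
})

test_that("one candidate per node is mined before pruning and maximality", {
  f <- fig1_dapg("ID")
  cands <- lapply(f$dapg$nodes, mine_from_node, dapg = f$dapg,
                  cfg = mining_config("deepest", "UNONE", "ID"),
                  net = f$net)
  expect_equal(length(cands), f$dapg$n_nodes)
  expect_equal(vapply(cands, `[[`, 0L, "seed_node"), 1:7)
})

test_that("maximality filtering removes contained vertex sets", {
  mk <- function(S, C, score, seed) {
    structure(list(S = S, C = C, score = score, seed_node = seed,
                   n_accepted = 1L), class = "dense_subgraph")
  }
  out <- filter_maximal(list(mk(1:3, 1:3, 3, 1L), mk(1:2, 1:2, 2, 2L)))
  expect_equal(length(out), 1L)
  expect_equal(out[[1L]]$S, 1:3)

  # identical vertex sets: one survivor, highest score then smallest seed
  out2 <- filter_maximal(list(mk(3:6, 3:4, 2, 4L), mk(3:6, 3:6, 4, 6L)))
  expect_equal(length(out2), 1L)
  expect_equal(out2[[1L]]$seed_node, 6L)

  out3 <- filter_maximal(list(mk(1:3, 1:3, 3, 1L), mk(4:6, 4:6, 3, 4L)))
  expect_equal(length(out3), 2L)
})

test_that("every mined subgraph is valid and outputs form an antichain", {
  n_checked <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    net <- random_network(sample(5:12, 1L), runif(1, 0.2, 0.6), seed)
    for (phi in c("ID", "FREQUENCY")) {
      for (trav in c("deepest", "sharing")) {
        cfg <- mining_config(trav, "UNONE", phi)
        mapping <- build_node_ordering(net, "first")
        mapped <- remap_network(net, mapping)
        dapg <- dapg_from_network(mapped, phi = phi)
        dsgs <- mine_all(dapg, cfg, mapped)
        for (d in dsgs) expect_true(is_valid_dsg(d, mapped))
        unions <- lapply(dsgs, function(d) union(d$S, d$C))
        if (length(unions) > 1L) {
          for (i in seq_along(unions)) {
            for (j in seq_along(unions)) {
              if (i != j) expect_false(all(unions[[i]] %in% unions[[j]]))
            }
          }
        }
        n_checked <- n_checked + length(dsgs)
      }
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("planted disjoint cliques are recovered exactly", {
  # brute-force clique enumeration is the oracle
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:4, 1L)
    sizes <- sample(3:5, k, replace = TRUE)
    offs <- cumsum(c(0L, sizes))
    edges <- do.call(rbind, lapply(seq_len(k), function(i) {
      t(combn(offs[i] + seq_len(sizes[i]), 2L))
    }))
    net <- ppi_network(edges, sprintf("P%02d", seq_len(sum(sizes))))
    pred <- predict_complexes(net, predict_config(
      mining = mining_config("deepest", "UNONE", "ID")))
    expect_equal(set_of_sets(pred$complexes),
                 set_of_sets(oracle_cliques(net)))
  }
})

test_that("weighted objectives favor heavier subgraphs", {
  # two triangles sharing no vertex; one has weight 1 edges, other 0.2
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                 c(4L, 5L), c(4L, 6L), c(5L, 6L))
  w <- c(1, 1, 1, 0.2, 0.2, 0.2)
  net <- ppi_network(edges, as.character(1:6), w, "USYM")
  mapping <- build_node_ordering(net, "first")
  mapped <- remap_network(net, mapping)
  dapg <- dapg_from_network(mapped, phi = "ID")
  dsgs <- mine_all(dapg, mining_config("deepest", "WEDGE", "ID"), mapped)
  scores <- vapply(dsgs, `[[`, 0, "score")
  unions <- lapply(dsgs, function(d) union(d$S, d$C))
  heavy <- which(vapply(unions, function(u) setequal(u, 1:3), NA))
  light <- which(vapply(unions, function(u) setequal(u, 4:6), NA))
  expect_length(heavy, 1L)
  expect_length(light, 1L)
  expect_equal(scores[heavy], 1)
  expect_equal(scores[light], 0.2)
})
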