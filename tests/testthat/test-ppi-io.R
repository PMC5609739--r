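test_that("edge-list parsing collapses duplicates, flips and self-loops", {
  p <- write_lines_tmp(c("A B", "B A", "A A"))
  net <- read_ppi(p, "UNONE")
  expect_equal(num_vertices(net), 2L)
  expect_equal(num_edges(net), 1L)
  expect_equal(net$weights, 1)

  p2 <- write_lines_tmp(c("A B 0.5", "B C 0.9"))
  net2 <- read_ppi(p2, "USYM")
  expect_equal(num_vertices(net2), 3L)
  expect_equal(num_edges(net2), 2L)
  ids <- match(c("A", "B"), net2$names)
  expect_equal(edge_weight(net2, ids[1], ids[2]), 0.5)

  # idempotent under duplication and orientation flips
  p3 <- write_lines_tmp(c("A B 0.5", "B C 0.9", "B A 0.5", "A B 0.5"))
  net3 <- read_ppi(p3, "USYM")
  expect_equal(net3$edges, net2$edges)
  expect_equal(net3$weights, net2$weights)
})

test_that("comments and mixed delimiters are accepted; UNONE drops weights", {
  p <- write_lines_tmp(c("# a comment", "A\tB\t0.3", "", "B C"))
  expect_message(net <- read_ppi(p, "UNONE"), "ignoring weight")
  expect_equal(num_edges(net), 2L)
  expect_true(all(net$weights == 1))
})

test_that("malformed lines and bad weights are rejected with line numbers", {
  expect_error(read_ppi(write_lines_tmp(c("A B", "C")), "UNONE"),
               "line 2")
  expect_error(read_ppi(write_lines_tmp("A B 1.5"), "USYM"),
               "outside \\[0, 1\\] on line 1")
  expect_error(read_ppi(write_lines_tmp("A B x"), "USYM"),
               "malformed weight on line 1")
})

test_that("the worked-example network has 7 proteins and 12 interactions", {
  fx <- fig1_fixture()
  lines <- apply(fx$network$edges, 1L, function(e) {
    paste(fx$network$names[e[1L]], fx$network$names[e[2L]])
  })
  net <- read_ppi(write_lines_tmp(lines), "UNONE")
  expect_equal(num_vertices(net), 7L)
  expect_equal(num_edges(net), 12L)
})

test_that("ordering schemes return permutations with the documented heads", {
  # star K1,3: center X has the highest degree
  star <- ppi_network(cbind(1L, 2:4), c("X", "A", "B", "C"))
  expect_equal(build_node_ordering(star, "degree")$order[1L], "X")
  expect_equal(build_node_ordering(star, "lexicographic")$order,
               c("A", "B", "C", "X"))
  expect_equal(build_node_ordering(star, "first")$order,
               c("X", "A", "B", "C"))
  # BFS from the hub visits leaves in name order; DFS likewise here
  expect_equal(build_node_ordering(star, "bfs")$order,
               c("X", "A", "B", "C"))
  expect_equal(build_node_ordering(star, "dfs")$order,
               c("X", "A", "B", "C"))

  for (seed in c(1L, 7L, 42L)) {
    net <- random_network(12, 0.3, seed)
    for (scheme in c("first", "lexicographic", "degree", "random",
                     "bfs", "dfs")) {
      ord <- build_node_ordering(net, scheme, seed = 99L)$order
      expect_setequal(ord, net$names)
      expect_equal(length(ord), length(unique(ord)))
    }
  }
})

test_that("the random ordering is reproducible for a fixed seed", {
  net <- random_network(15, 0.3, 3L)
  o1 <- build_node_ordering(net, "random", seed = 11L)
  o2 <- build_node_ordering(net, "random", seed = 11L)
  o3 <- build_node_ordering(net, "random", seed = 12L)
  expect_identical(o1$order, o2$order)
  expect_false(identical(o1$order, o3$order))
  expect_error(build_node_ordering(net, "random"), "seed")
})

test_that("traversal orderings restart across disconnected components", {
  # two components: triangle D,E,F plus edge A-B
  net <- ppi_network(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(4L, 5L)),
                     c("D", "E", "F", "A", "B"))
  ord <- build_node_ordering(net, "bfs")$order
  # start at highest degree (D,E,F tie -> D), then restart at A
  expect_equal(ord, c("D", "E", "F", "A", "B"))
})

test_that("complex-set files round-trip and deduplicate", {
  cs <- read_complex_set(write_lines_tmp(c("A B C", "A B C")))
  expect_equal(length(cs$complexes), 1L)

  cs2 <- read_complex_set(write_lines_tmp(c("A B", "C D E")))
  expect_equal(lengths(cs2$complexes), c(2L, 3L))

  path <- tempfile()
  write_complex_set(complex_set(list(c("B", "A"))), path)
  expect_equal(readLines(path), "A B")

  rt <- read_complex_set({ write_complex_set(cs2, path); path })
  expect_equal(set_of_sets(rt$complexes), set_of_sets(cs2$complexes))

  expect_warning(empty <- read_complex_set(write_lines_tmp(character())),
                 "no complexes")
  expect_equal(length(empty$complexes), 0L)
})

test_that("reference merging keeps one copy per label or member set", {
  a <- complex_set(list(c("p1", "p2")), labels = "X")
  b_same_label <- complex_set(list(c("p1", "p2", "p3")), labels = "X")
  b_same_members <- complex_set(list(c("p1", "p2")), labels = "Y")
  b_different <- complex_set(list(c("p3", "p4")), labels = "Y")

  expect_equal(length(merge_references(a, b_same_label)$complexes), 1L)
  expect_equal(length(merge_references(a, b_same_members)$complexes), 1L)
  expect_equal(length(merge_references(a, b_different)$complexes), 2L)

  # commutative on member-set collections when labels don't clash
  set.seed(5)
  x <- random_complexes(4, sprintf("u%d", 1:10))
  y <- random_complexes(3, sprintf("u%d", 1:10))
  expect_equal(set_of_sets(merge_references(x, y)$complexes),
               set_of_sets(merge_references(y, x)$complexes))
})

test_that("mapping files round-trip and validate", {
  net <- random_network(6, 0.5, 2L)
  m <- build_node_ordering(net, "degree")
  path <- tempfile()
  write_node_mapping(m, path)
  m2 <- read_node_mapping(path)
  expect_equal(m2$order, m$order)
  expect_error(read_node_mapping(write_lines_tmp(c("A 1", "A 2"))),
               "distinct")
})
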