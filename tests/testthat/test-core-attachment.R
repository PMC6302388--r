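test_that("maximal clique enumeration matches small hand cases", {
  # triangle plus pendant edge: the pendant never reaches size 3
  net <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("c", "d")))
  expect_identical(enumerate_maximal_cliques(net, 3L),
                   list(c("a", "b", "c")))

  # two triangles sharing the edge b-c
  net2 <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                            c("b", "d"), c("c", "d")))
  expect_identical(enumerate_maximal_cliques(net2, 3L),
                   list(c("a", "b", "c"), c("b", "c", "d")))
  expect_identical(oracle_max_cliques(net2, 3L),
                   enumerate_maximal_cliques(net2, 3L))
})

test_that("clique enumeration agrees with the exhaustive oracle", {
  set.seed(99)
  for (rep in 1:8) {
    net <- rand_gnp_network(10L, stats::runif(1L, 0.2, 0.6))
    expect_identical(enumerate_maximal_cliques(net, 3L),
                     oracle_max_cliques(net, 3L))
  }
})

test_that("density score sums weights over unordered member pairs", {
  ids <- c("a", "b", "c", "d")
  net <- ppi_network(t(utils::combn(ids, 2L)))
  W1 <- make_weighted(net, stats::setNames(
    rep(1, 3L), c("a b", "a c", "b c")))
  expect_equal(density_score(c("a", "b", "c"), W1), 3)
  Wh <- make_weighted(net, stats::setNames(
    rep(0.5, 6L), apply(utils::combn(ids, 2L), 2L, paste, collapse = " ")))
  expect_equal(density_score(ids, Wh), 3)
  expect_equal(density_score(ids, make_weighted(net, list())), 0)
})

test_that("seed selection follows the subtract-and-prune trace", {
  # candidates {a,b,c} (score 3) and {b,c,d} (score 2): the loser shrinks
  # to {d} after subtraction and is dropped
  net <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("b", "d"), c("c", "d")))
  W <- make_weighted(net, list("a b" = 1, "a c" = 1, "b c" = 1,
                               "b d" = 0.5, "c d" = 0.5))
  cliques <- enumerate_maximal_cliques(net, 3L)
  expect_identical(select_seed_cores(cliques, W, 3L),
                   list(c("a", "b", "c")))

  # two disjoint triangles: both survive, higher score first
  net2 <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                            c("x", "y"), c("x", "z"), c("y", "z")))
  W2 <- make_weighted(net2, list("a b" = 0.2, "a c" = 0.2, "b c" = 0.2,
                                 "x y" = 1, "x z" = 1, "y z" = 1))
  expect_identical(select_seed_cores(enumerate_maximal_cliques(net2, 3L),
                                     W2, 3L),
                   list(c("x", "y", "z"), c("a", "b", "c")))

  # a single candidate is the single seed
  expect_identical(select_seed_cores(list(c("a", "b", "c")), W, 3L),
                   list(c("a", "b", "c")))
})

test_that("seed cores stay disjoint and clique-complete on random graphs", {
  set.seed(4)
  for (rep in 1:5) {
    net <- rand_gnp_network(14L, 0.35)
    n <- length(net$proteins)
    W <- matrix(stats::runif(n * n), n, n,
                dimnames = list(net$proteins, net$proteins))
    W <- (W + t(W)) / 2
    W[adjacency_matrix(net) == 0] <- 0
    seeds <- select_seed_cores(enumerate_maximal_cliques(net, 3L), W, 3L)
    members <- unlist(seeds)
    expect_identical(anyDuplicated(members), 0L)
    A <- adjacency_matrix(net)
    for (core in seeds) {
      sub <- A[core, core]
      expect_true(all(sub[upper.tri(sub)] == 1))
      expect_gte(length(core), 3L)
    }
  }
})

test_that("correlation score is the mean weight into the core", {
  ids <- c("a", "b", "c", "p")
  net <- ppi_network(rbind(c("p", "a"), c("p", "b"), c("a", "b"),
                           c("a", "c"), c("b", "c")))
  W <- make_weighted(net, list("a p" = 1, "b p" = 0.5))
  core <- c("a", "b", "c")
  expect_equal(correlation_score("p", core, W), 0.5)
  expect_equal(correlation_score("p", core, make_weighted(net, list())), 0)
  Wall <- make_weighted(net, list("a p" = 1, "b p" = 1))
  expect_equal(correlation_score("p", c("a", "b"), Wall), 1)
  expect_error(correlation_score("a", core, W), "member")
})

test_that("attachment respects the strict threshold and allows sharing", {
  net <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("c", "d")))
  W <- make_weighted(net, list("a b" = 1, "a c" = 1, "b c" = 1,
                               "c d" = 0.96))
  cs <- attach_and_assemble(list(c("a", "b", "c")), net, W, theta = 0.3)
  expect_identical(cs$complexes, list(c("a", "b", "c", "d")))
  expect_identical(cs$attachments, list("d"))

  # theta = 1 with weights <= 1: strict comparison admits nothing
  W1 <- make_weighted(net, list("a b" = 1, "a c" = 1, "b c" = 1,
                                "c d" = 1))
  cs1 <- attach_and_assemble(list(c("a", "b", "c")), net, W1, theta = 1)
  expect_identical(cs1$complexes, list(c("a", "b", "c")))

  # one protein may attach to two different cores
  net2 <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                            c("x", "y"), c("x", "z"), c("y", "z"),
                            c("p", "a"), c("p", "x")))
  w2 <- stats::setNames(rep(1, 8L),
                        c("a b", "a c", "b c", "x y", "x z", "y z",
                          "a p", "p x"))
  W2 <- make_weighted(net2, as.list(w2))
  cs2 <- attach_and_assemble(list(c("a", "b", "c"), c("x", "y", "z")),
                             net2, W2, theta = 0.3)
  expect_identical(cs2$complexes, list(c("a", "b", "c", "p"),
                                       c("p", "x", "y", "z")))
})

test_that("disjoint cliques with uniform weights are returned verbatim", {
  blocks <- list(c("a", "b", "c", "d"), c("e", "f", "g"),
                 c("h", "i", "j", "k", "l"))
  edges <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2L))))
  net <- ppi_network(edges)
  w <- stats::setNames(rep(0.8, nrow(edges)),
                       apply(edges, 1L, paste, collapse = " "))
  W <- make_weighted(net, as.list(w))
  cs <- detect_complexes(net, W, detection_config(theta = 0.3))
  expect_setequal(vapply(cs$complexes, paste, character(1L), collapse = " "),
                  vapply(blocks, paste, character(1L), collapse = " "))
  expect_identical(cs$complexes, cs$cores)
})

test_that("a network with no qualifying clique yields an empty set", {
  net <- ppi_network(rbind(c("a", "b"), c("b", "c")))
  W <- make_weighted(net, list("a b" = 1, "b c" = 1))
  expect_warning(cs <- detect_complexes(net, W), "no maximal clique")
  expect_length(cs, 0L)
})
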