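# Small attributed instances for embedding tests.
rand_instance <- function(n, p, m = 4L) {
  net <- rand_gnp_network(n, p)
  O <- matrix(stats::rbinom(n * m, 1L, 0.5), n, m,
              dimnames = list(net$proteins, NULL))
  ad <- structure(list(proteins = net$proteins,
                       terms = sprintf("t%d", seq_len(m)), O = O, S = NULL),
                  class = "attribute_data")
  list(net = net, attr = build_affinity(ad))
}

test_that("the joint loss matches hand-collapsed special cases", {
  inst <- withr::with_seed(1, rand_instance(6L, 0.5))
  S <- inst$attr$S
  phi0 <- matrix(0, 6L, 3L)
  expect_equal(gane_loss(phi0, inst$net, S, lambda = 1),
               sum(S^2) - sum(diag(S)^2))

  # two nodes, one edge, identical vectors, s_12 = |phi|^2 -> exact fit
  net2 <- ppi_network(cbind("a", "b"))
  phi <- rbind(c(0.6, 0.8), c(0.6, 0.8))
  S2 <- matrix(1, 2L, 2L)
  expect_equal(gane_loss(phi, net2, S2, lambda = 1), 0)

  expect_error(gane_loss(matrix(0, 3L, 2L), inst$net, S, 1), "mismatch")
})

test_that("the joint loss equals the brute-force double loop", {
  set.seed(42)
  for (rep in 1:10) {
    inst <- rand_instance(6L, 0.5)
    phi <- matrix(stats::rnorm(6L * 3L), 6L, 3L)
    lam <- stats::runif(1L, 0, 2)
    expect_lt(abs(gane_loss(phi, inst$net, inst$attr$S, lam) -
                    oracle_loss(phi, adjacency_matrix(inst$net),
                                inst$attr$S, lam)),
              1e-10)
  }
})

test_that("coordinate descent is monotone, deterministic and stationary", {
  set.seed(7)
  inst <- rand_instance(8L, 0.4)
  cfg <- embedding_config(d = 4L, lambda = 0.5, max_sweeps = 200L,
                          tol = 1e-12, seed = 99L)
  emb <- fit_embedding(inst$net, inst$attr, cfg)
  expect_true(all(is.finite(emb$phi)))
  expect_true(all(diff(emb$trace) <= 1e-9 * (1 + abs(emb$trace[-1L]))))
  expect_lte(emb$loss, emb$trace[1L])

  emb2 <- fit_embedding(inst$net, inst$attr, cfg)
  expect_identical(emb$trace, emb2$trace)
  expect_identical(emb$phi, emb2$phi)

  g <- numeric_gradient(emb$phi, inst$net, inst$attr$S, cfg$lambda)
  expect_lt(max(abs(g)), 1e-5)
})

test_that("pure-topology limit collapses a connected path", {
  ids <- sprintf("v%d", 1:5)
  net <- ppi_network(cbind(ids[-5L], ids[-1L]))
  ad <- build_affinity(build_attribute_matrix(
    net, data.frame(protein = character(), term = character())))
  emb <- fit_embedding(net, ad, embedding_config(d = 3L, lambda = 0,
                                                 max_sweeps = 200L,
                                                 tol = 1e-12, seed = 2L))
  expect_lt(emb$loss, 1e-6)
})

test_that("cosine reweighting follows the edge support", {
  net <- ppi_network(rbind(c("a", "b"), c("b", "c")))
  phi <- rbind(a = c(1, 0), b = c(0, 1), c = c(0, 2))
  emb <- structure(list(phi = phi), class = "gane_embedding")
  W <- build_weighted_adjacency(emb, net)
  expect_equal(W["a", "b"], 0)   # orthogonal vectors
  expect_equal(W["b", "c"], 1)   # parallel vectors
  expect_equal(W["a", "c"], 0)   # non-edge
  expect_identical(W, t(W))

  # zero vector gives weight 0; clamping floors negatives
  phi2 <- rbind(a = c(0, 0), b = c(0, 1), c = c(0, -1))
  emb2 <- structure(list(phi = phi2), class = "gane_embedding")
  W2 <- build_weighted_adjacency(emb2, net)
  expect_equal(W2["a", "b"], 0)
  expect_equal(W2["b", "c"], -1)
  W2c <- build_weighted_adjacency(emb2, net, clamp = TRUE)
  expect_equal(W2c["b", "c"], 0)
})

test_that("weight support implies adjacency on random instances", {
  set.seed(13)
  inst <- rand_instance(12L, 0.3)
  emb <- fit_embedding(inst$net, inst$attr,
                       embedding_config(d = 4L, lambda = 0.1,
                                        max_sweeps = 30L, seed = 5L))
  W <- build_weighted_adjacency(emb, inst$net)
  A <- adjacency_matrix(inst$net)
  expect_true(all(A[W != 0] == 1))
  expect_true(all(W >= -1 - 1e-12 & W <= 1 + 1e-12))
})

test_that("embedding matrices round-trip through the TSV export", {
  set.seed(17)
  inst <- rand_instance(6L, 0.5)
  emb <- fit_embedding(inst$net, inst$attr,
                       embedding_config(d = 3L, max_sweeps = 5L, seed = 1L))
  f <- withr::local_tempfile()
  write_embedding(emb, f)
  back <- read_embedding(f)
  expect_identical(rownames(back$phi), rownames(emb$phi))
  expect_equal(back$phi, emb$phi, tolerance = 1e-10)
})
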