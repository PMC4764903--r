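test_that("benchmark centralities match hand and oracle values", {
  expect_equal(unname(degree_centrality(toy_graph("path", 3))), c(1, 2, 1))

  # k-shell: trees collapse to shell 1, cliques to n-1, pendants peel first
  expect_equal(unname(kshell(toy_graph("star", 5))), rep(1, 6))
  expect_equal(unname(kshell(toy_graph("complete", 4))), rep(3, 4))
  expect_equal(unname(kshell(toy_graph("triangle_pendant"))), c(2, 2, 2, 1))
  net <- random_graph("er", n = 35, p = 0.15, rng_seed = 21)
  ks <- kshell(net)
  expect_equal(ks[names(ks)], oracle_kshell(net)[names(ks)])

  # eigenvector: uniform on K_n; exact ratios on path(3) and star
  vK <- eigenvector_centrality(toy_graph("complete", 5))
  expect_equal(unname(vK), rep(0.2, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  vP <- eigenvector_centrality(toy_graph("path", 3))
  expect_equal(unname(vP["1"] / vP["0"]), sqrt(2), tolerance = 1e-8)
  vS <- eigenvector_centrality(toy_graph("star", 3))
  expect_equal(unname(vS["0"] / vS["1"]), sqrt(3), tolerance = 1e-8)
  expect_equal(attr(vS, "lambda"), sqrt(3), tolerance = 1e-8)
  # positive, unit sum, and consistent with igraph's ARPACK route
  v <- eigenvector_centrality(net)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1)
  vi <- igraph::eigen_centrality(net)$vector
  expect_equal(unname(v), unname(vi / sum(vi)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("propagation matrix is beta*A + (1-mu)*I", {
  g <- toy_graph("path", 3)
  A <- build_adjacency(g)
  H <- propagation_matrix(g, spreading_params(0.1, 0.5, 1))
  expect_equal(as.matrix(H), as.matrix(0.1 * A + 0.5 * Matrix::Diagonal(3)),
               ignore_attr = TRUE)
  expect_equal(as.matrix(propagation_matrix(g, spreading_params(0.2, 1, 1))),
               as.matrix(0.2 * A), ignore_attr = TRUE)
  expect_equal(as.matrix(propagation_matrix(g, spreading_params(0, 0, 1))),
               diag(3), ignore_attr = TRUE)
})

test_that("linearized infection probabilities follow the recursion", {
  g <- toy_graph("path", 3)
  # one step: beta on each neighbour of the seed
  x1 <- infection_probabilities(g, spreading_params(0.1, 1, 1), "1")
  expect_equal(unname(x1), c(0.1, 0, 0.1))
  # two steps, mu = 1: newly infected at step 2 adds beta^2 A^2 e_seed
  x2 <- infection_probabilities(g, spreading_params(0.1, 1, 2), "1")
  expect_equal(unname(x2), c(0.1, 0.02, 0.1))
  expect_equal(unname(infection_probabilities(g, spreading_params(0, 0.5, 4), "0")),
               rep(0, 3))
})

test_that("DS centrality matches hand values and the dense-power oracle", {
  g <- toy_graph("path", 3)
  expect_equal(unname(ds_centrality(g, spreading_params(0.1, 1, 2))),
               c(0.12, 0.22, 0.12))
  # t = 1 is beta * degree on any network
  net <- random_graph("ba", n = 60, m = 2, rng_seed = 31)
  expect_equal(unname(ds_centrality(net, spreading_params(0.07, 0.4, 1))),
               unname(0.07 * degree_centrality(net)))
  # vertex-transitive symmetry
  s <- ds_centrality(toy_graph("complete", 3), spreading_params(0.3, 0.6, 7))
  expect_equal(max(s) - min(s), 0, tolerance = 1e-14)
  # general (beta, mu, t) against dense matrix powers
  for (mu in c(0, 0.3, 1)) {
    p <- spreading_params(0.15, mu, 6)
    expect_equal(unname(ds_centrality(net, p)),
                 unname(oracle_ds_dense(net, 0.15, mu, 6)), tolerance = 1e-10)
  }
  # mu = 1 walk-count form: sum_r beta^r A^r L
  A <- as.matrix(build_adjacency(net))
  walks <- Reduce(`+`, lapply(1:5, function(r) {
    0.1^r * as.numeric(matpow(A, r) %*% rep(1, nrow(A)))
  }))
  expect_equal(unname(ds_centrality(net, spreading_params(0.1, 1, 5))),
               walks, tolerance = 1e-10)
})

test_that("DS scores are non-negative, monotone in t, permutation-equivariant", {
  net <- random_graph("er", n = 40, p = 0.12, rng_seed = 41)
  prev <- rep(0, igraph::vcount(net))
  for (t in 1:8) {
    s <- ds_centrality(net, spreading_params(0.08, 0.5, t))
    expect_true(all(s >= prev - 1e-14))
    prev <- s
  }
  # relabeling nodes permutes every centrality identically
  labels <- igraph::V(net)$name
  perm <- withr::with_seed(5, sample(labels))
  el <- igraph::as_edgelist(net, names = TRUE)
  el[] <- perm[match(el, labels)]
  net2 <- make_network(el)
  p <- spreading_params(0.1, 0.7, 5)
  for (fn in list(function(g) ds_centrality(g, p),
                  degree_centrality,
                  kshell,
                  eigenvector_centrality)) {
    a <- fn(net)
    b <- fn(net2)
    expect_equal(unname(b[perm[match(labels, labels)]]), unname(a),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("infinite-horizon limit solves the series in closed form", {
  expect_equal(unname(ds_centrality_limit(toy_graph("complete", 2), 0.5, 1)),
               c(1, 1))
  expect_equal(unname(ds_centrality_limit(toy_graph("path", 3), 0, 1)),
               rep(0, 3))
  # sub-threshold on path(3): 0.5 * sqrt(2) < 1 converges
  expect_silent(ds_centrality_limit(toy_graph("path", 3), 0.5, 1))
  # 0.8 * sqrt(2) > 1 diverges, error names the condition
  expect_error(ds_centrality_limit(toy_graph("path", 3), 0.8, 1), "divergent")
  expect_error(ds_centrality_limit(toy_graph("path", 3), 0.1, 0), "mu")
  # limit equals a long truncation of the series
  net <- random_graph("er", n = 30, p = 0.15, rng_seed = 51)
  l1 <- network_summary(net)$lambda1
  beta <- 0.8 / l1
  expect_equal(unname(ds_centrality_limit(net, beta, 1)),
               unname(ds_centrality(net, spreading_params(beta, 1, 300))),
               tolerance = 1e-9)
})

test_that("spectral form reproduces the iterative form", {
  net <- random_graph("ba", n = 50, m = 2, rng_seed = 61)
  for (mu in c(0, 0.5, 1)) {
    p <- spreading_params(0.12, mu, 7)
    expect_equal(unname(ds_spectral(net, p)), unname(ds_centrality(net, p)),
                 tolerance = 1e-9)
  }
  # t = 1 reduces to beta * degree
  expect_equal(unname(ds_spectral(net, spreading_params(0.05, 1, 1))),
               unname(0.05 * degree_centrality(net)), tolerance = 1e-10)
  # eigendecomposition satisfies A q = lambda q, descending order
  sd <- spectral_decomposition(net)
  A <- as.matrix(build_adjacency(net))
  expect_true(all(diff(sd$values) <= 1e-12))
  expect_lt(max(abs(A %*% sd$vectors - sd$vectors %*% diag(sd$values))), 1e-8)
  expect_true(all(sd$vectors[, 1] > 0))
})

test_that("ranking converges to the eigenvector centrality above threshold", {
  net <- random_graph("ba", n = 100, m = 3, rng_seed = 71)
  l1 <- network_summary(net)$lambda1
  v <- as.numeric(eigenvector_centrality(net))
  taus <- vapply(c(5, 30, 100), function(t) {
    kendall_tau(as.numeric(ds_centrality(net, spreading_params(1.1 / l1, 1, t))), v)
  }, 1)
  expect_true(all(diff(taus) >= -1e-12))
  expect_gte(taus[3], 0.99)
})

test_that("contact kernel row-normalizes and rejects isolated nodes", {
  star <- toy_graph("star", 3)
  p <- spreading_params(0.2, 1, 2)
  s <- ds_centrality(star, p, kernel = "contact")
  # D^-1 A on the star: center row 1/3 each leaf, leaf rows 1 on the center
  M <- diag(1 / unname(degree_centrality(star))) %*%
    as.matrix(build_adjacency(star))
  expected <- 0.2 * M %*% rep(1, 4) + 0.2 * M %*% (0.2 * M %*% rep(1, 4))
  expect_equal(unname(s), as.numeric(expected))
  iso <- make_network(cbind("a", "b"), isolated = "c")
  expect_error(ds_centrality(iso, p, kernel = "contact"), "isolated")
})
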