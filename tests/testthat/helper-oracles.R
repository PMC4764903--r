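# Independent brute-force oracles, deliberately naive: each re-derives a
# quantity from first principles by a different route than the package.

# k-shell by literal iterative pruning on an edge list.
oracle_kshell <- function(net) {
  labels <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)
  alive <- labels
  shell <- setNames(rep(0, length(labels)), labels)
  k <- 0
  while (length(alive)) {
    repeat {
      deg <- setNames(rep(0, length(alive)), alive)
      keep <- el[, 1] %in% alive & el[, 2] %in% alive
      for (r in which(keep)) {
        deg[el[r, 1]] <- deg[el[r, 1]] + 1
        deg[el[r, 2]] <- deg[el[r, 2]] + 1
      }
      drop <- alive[deg[alive] <= k]
      if (!length(drop)) break
      shell[drop] <- k
      alive <- setdiff(alive, drop)
    }
    k <- k + 1
  }
  shell
}

# DS centrality by dense matrix powers of H (the algebra the package
# evaluates with matrix-vector products).
oracle_ds_dense <- function(net, beta, mu, t) {
  A <- as.matrix(build_adjacency(net))
  n <- nrow(A)
  H <- beta * A + (1 - mu) * diag(n)
  Hp <- diag(n)
  acc <- numeric(n)
  for (r in seq_len(t)) {
    acc <- acc + beta * as.numeric(A %*% Hp %*% rep(1, n))
    Hp <- Hp %*% H
  }
  setNames(acc, rownames(A))
}

# Kendall tau-a by an explicit double loop over pairs.
oracle_kendall <- function(y, z) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(y[i] - y[j]) * sign(z[i] - z[j])
    }
  }
  2 * s / (n * (n - 1))
}

matpow <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

# Number of nodes within graph distance t of a seed (BFS layers).
oracle_bfs_reach <- function(net, seed_label, t) {
  d <- igraph::distances(net, v = seed_label)
  sum(d <= t)
}

expect_same_ranking <- function(a, b) {
  expect_identical(order(a, names(a)), order(b, names(b)))
  expect_equal(rank(a, ties.method = "average"),
               rank(b, ties.method = "average"),
               ignore_attr = TRUE)
}
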