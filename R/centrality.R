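# Dynamics-sensitive (DS) centrality in its four equivalent forms, plus the
# degree / k-shell / eigenvector benchmarks it is compared against.
#
# The DS score of node i at horizon t is
#     S_i(t) = sum_{r=1..t} (beta * A %*% H^(r-1) %*% L)_i,
# with H = beta*A + (1-mu)*I and L the all-ones vector: a walk count in
# which every walk of length r is weighted by the chance that the infection
# survives long enough to traverse it. At t = 1 it reduces to beta * degree;
# for beta*lambda1 + 1 - mu < 1 it has a finite t -> Inf limit; as t and
# beta grow, its ranking converges to the eigenvector centrality.

#' Spreading parameters
#'
#' Bundles the spreading rate `beta`, the recovery rate `mu` (`mu = 0` is
#' the SI model, `mu = 1` the one-shot SIR used throughout) and the time
#' horizon `t` (synchronous steps).
#'
#' @param beta per-contact infection probability in \[0, 1\].
#' @param mu per-step recovery probability in \[0, 1\].
#' @param t non-negative integer horizon.
#' @return a list of class `"spreading_params"`.
#' @export
spreading_params <- function(beta, mu = 1, t = 5L) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1,
            is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1,
            is.numeric(t), length(t) == 1, t >= 0, t == round(t))
  structure(list(beta = beta, mu = mu, t = as.integer(t)),
            class = "spreading_params")
}

#' @export
print.spreading_params <- function(x, ...) {
  cat(sprintf("Spreading parameters: beta = %g, mu = %g, t = %d\n",
              x$beta, x$mu, x$t))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "spreading_params")) return(params)
  do.call(spreading_params, as.list(params))
}

#' Degree centrality
#'
#' @param x a network or adjacency matrix.
#' @return named numeric vector of node degrees (adjacency row sums).
#' @export
degree_centrality <- function(x) {
  A <- as_adjacency_input(x)
  structure(Matrix::rowSums(A), names = rownames(A))
}

#' k-shell index (coreness)
#'
#' Layer at which each node is removed during iterative k-core pruning:
#' all nodes of degree <= k are removed (re-checking after every removal
#' wave) before k is incremented. Every node of a tree has shell 1;
#' isolated nodes have shell 0.
#'
#' @param net a network ([igraph::graph]).
#' @return named integer-valued vector of shell indices.
#' @export
kshell <- function(net) {
  stopifnot(igraph::is_igraph(net))
  cs <- igraph::coreness(net)
  structure(as.numeric(cs), names = igraph::V(net)$name)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the adjacency matrix, strictly positive on a
#' connected network (Perron-Frobenius) and normalized to unit sum. The
#' power iteration runs on A + I, which shares A's leading eigenvector but
#' is primitive, so the iteration converges even on bipartite graphs.
#'
#' @param x a network or adjacency matrix (connected).
#' @param tol convergence threshold on the max successive-iterate change.
#' @param max_iter iteration cap.
#' @return named numeric vector summing to 1, with attribute `"lambda"`
#'   (the leading eigenvalue of A).
#' @export
eigenvector_centrality <- function(x, tol = 1e-10, max_iter = 10000L) {
  A <- as_adjacency_input(x)
  n <- nrow(A)
  v <- rep(1 / n, n)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v
    s <- sum(w)
    if (s <= 0) stop("power iteration collapsed; is the network connected?")
    w <- w / s
    if (max(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) {
    stop("eigenvector centrality did not converge in ", max_iter,
         " iterations (residual ", format(max(abs(w - v))), ")")
  }
  if (any(v <= 0)) stop("non-positive entries; is the network connected?")
  lam <- sum(v * as.numeric(A %*% v)) / sum(v * v)
  structure(v, names = rownames(A), lambda = lam)
}

#' Propagation matrix H = beta * A + (1 - mu) * I
#'
#' One synchronous step of the linearized dynamics: `beta * A` transmits
#' along edges, `(1 - mu) * I` keeps a node infectious with probability
#' 1 - mu. Its eigenvalues are `beta * lambda_i + 1 - mu`.
#'
#' @param x a network or adjacency matrix.
#' @param params [spreading_params()].
#' @return sparse symmetric `Matrix`.
#' @export
propagation_matrix <- function(x, params) {
  A <- as_adjacency_input(x)
  params <- as_params(params)
  params$beta * A + (1 - params$mu) * Matrix::Diagonal(nrow(A))
}

resolve_node <- function(x, node, labels) {
  if (is.character(node)) {
    idx <- match(node, labels)
    if (is.na(idx)) stop("unknown node label '", node, "'")
    return(idx)
  }
  node <- as.integer(node)
  if (node < 1 || node > length(labels)) stop("node index out of range")
  node
}

#' Linearized cumulative infection probabilities
#'
#' The vector x(t) = sum_{r=1..t} beta * A %*% H^(r-1) %*% e_seed: the
#' linear (mean-field) approximation of the cumulative probability that
#' each node gets infected within t steps when `seed` starts infected.
#' The linearization overestimates every entry and entries may exceed 1;
#' they are deliberately not capped.
#'
#' @param x a network or adjacency matrix.
#' @param params [spreading_params()].
#' @param seed seed node (label or 1-based index).
#' @return named numeric vector x(t).
#' @export
infection_probabilities <- function(x, params, seed) {
  A <- as_adjacency_input(x)
  params <- as_params(params)
  idx <- resolve_node(x, seed, rownames(A))
  H <- propagation_matrix(A, params)
  w <- numeric(nrow(A))
  w[idx] <- 1
  acc <- numeric(nrow(A))
  for (r in seq_len(params$t)) {
    acc <- acc + params$beta * as.numeric(A %*% w)
    w <- as.numeric(H %*% w)
  }
  structure(acc, names = rownames(A))
}

contact_kernel <- function(A) {
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) {
    stop("contact kernel D^-1 A undefined: the network has isolated nodes")
  }
  Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Dynamics-sensitive centrality (iterative form)
#'
#' S(t) = sum_{r=1..t} beta * A %*% H^(r-1) %*% L, evaluated with t sparse
#' matrix-vector products (never dense matrix powers). With `mu = 1` this
#' is the walk-count form sum_r beta^r * (A^r %*% L): the number of walks
#' of each length r leaving every node, geometrically damped by beta^r.
#' `kernel = "contact"` substitutes the row-normalized matrix D^-1 A for A
#' throughout, matching a variant dynamics where an infected node contacts
#' one uniformly chosen neighbour per step.
#'
#' @param x a network or adjacency matrix.
#' @param params [spreading_params()] with `t >= 1`.
#' @param kernel `"adjacency"` (default) or `"contact"`.
#' @return named numeric score vector.
#' @export
ds_centrality <- function(x, params, kernel = c("adjacency", "contact")) {
  A <- as_adjacency_input(x)
  params <- as_params(params)
  kernel <- match.arg(kernel)
  stopifnot(params$t >= 1)
  M <- if (kernel == "contact") contact_kernel(A) else A
  H <- params$beta * M + (1 - params$mu) * Matrix::Diagonal(nrow(A))
  w <- rep(1, nrow(A))
  acc <- numeric(nrow(A))
  for (r in seq_len(params$t)) {
    acc <- acc + params$beta * as.numeric(M %*% w)
    w <- as.numeric(H %*% w)
  }
  structure(acc, names = rownames(A))
}

#' Infinite-horizon DS centrality
#'
#' The t -> Inf limit of [ds_centrality()], finite exactly when
#' beta * lambda1 + 1 - mu < 1 (equivalently beta/mu < 1/lambda1, the
#' epidemic threshold). Computed without series truncation by solving
#' (I - H) y = L and returning beta * A %*% y.
#'
#' @param x a network or adjacency matrix.
#' @param beta spreading rate.
#' @param mu recovery rate, must be positive.
#' @return named numeric score vector.
#' @export
ds_centrality_limit <- function(x, beta, mu = 1) {
  A <- as_adjacency_input(x)
  stopifnot(beta >= 0, beta <= 1, mu > 0, mu <= 1)
  l1 <- lambda1(A)
  if (beta * l1 + 1 - mu >= 1) {
    stop("divergent series: beta*lambda1 + 1 - mu = ",
         format(beta * l1 + 1 - mu),
         " >= 1, so S(t) grows without bound as t -> Inf ",
         "(requires beta/mu < 1/lambda1 = ", format(1 / l1), ")")
  }
  n <- nrow(A)
  H <- beta * A + (1 - mu) * Matrix::Diagonal(n)
  y <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - H, rep(1, n)))
  structure(beta * as.numeric(A %*% y), names = rownames(A))
}

#' Spectral decomposition of the adjacency matrix
#'
#' Dense symmetric eigendecomposition with eigenvalues sorted descending
#' and a deterministic sign convention: the leading eigenvector is oriented
#' all-positive, every other eigenvector so its largest-magnitude entry is
#' positive.
#'
#' @param x a network or adjacency matrix.
#' @return list with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
spectral_decomposition <- function(x) {
  A <- as_adjacency_input(x)
  ed <- eigen(as.matrix(A), symmetric = TRUE)
  Q <- ed$vectors
  if (sum(Q[, 1]) < 0) Q[, 1] <- -Q[, 1]
  for (j in seq_len(ncol(Q))[-1]) {
    k <- which.max(abs(Q[, j]))
    if (Q[k, j] < 0) Q[, j] <- -Q[, j]
  }
  rownames(Q) <- rownames(A)
  list(values = ed$values, vectors = Q)
}

#' Dynamics-sensitive centrality (spectral form)
#'
#' Assembles S(t) from the eigendecomposition of A: writing
#' h_i = beta*lambda_i + 1 - mu, the mode-i contribution is
#' beta * lambda_i * sum_{r=1..t} h_i^(r-1) * (q_i' L) * q_i.
#' Agrees with the iterative [ds_centrality()] to floating-point accuracy;
#' as t and beta grow the leading mode dominates and the ranking converges
#' to the eigenvector centrality q_1. Dense path, intended for n up to a
#' few thousand.
#'
#' @param x a network or adjacency matrix.
#' @param params [spreading_params()] with `t >= 1`.
#' @return named numeric score vector.
#' @export
ds_spectral <- function(x, params) {
  A <- as_adjacency_input(x)
  params <- as_params(params)
  stopifnot(params$t >= 1)
  sd <- spectral_decomposition(A)
  h <- params$beta * sd$values + 1 - params$mu
  # geometric sums sum_{r=1..t} h^(r-1), computed termwise for stability
  pows <- outer(h, 0:(params$t - 1L), `^`)
  g <- rowSums(pows)
  qL <- as.numeric(crossprod(sd$vectors, rep(1, nrow(A))))
  weights <- params$beta * sd$values * g * qL
  structure(as.numeric(sd$vectors %*% weights),
            names = rownames(A))
}

#' Compute a centrality by name
#'
#' Dispatch helper used by the evaluation module and the CLI.
#'
#' @param net a network.
#' @param method `"degree"`, `"kshell"`, `"eigenvector"`, `"ds"` or
#'   `"ds_limit"`.
#' @param params [spreading_params()] (required for `"ds"`/`"ds_limit"`).
#' @param kernel passed to [ds_centrality()].
#' @return named numeric score vector.
#' @export
centrality <- function(net, method = c("degree", "kshell", "eigenvector",
                                       "ds", "ds_limit"),
                       params = NULL, kernel = "adjacency") {
  method <- match.arg(method)
  switch(method,
    degree = degree_centrality(net),
    kshell = kshell(net),
    eigenvector = eigenvector_centrality(net),
    ds = ds_centrality(net, params, kernel = kernel),
    ds_limit = {
      params <- as_params(params)
      ds_centrality_limit(net, params$beta, params$mu)
    }
  )
}
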