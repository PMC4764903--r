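# Discrete-time SIR/SI dynamics with synchronous updates. Status coding:
# 0 = susceptible, 1 = infected, 2 = recovered. Within a step, infections
# are resolved before recoveries and both use the infected set from the
# start of the step; a node infected at step t neither transmits nor
# recovers before step t + 1. A susceptible node with m infected
# neighbours is infected with probability 1 - (1 - beta)^m (independent
# per-edge contacts) — the exact rule whose linearization (m * beta) the
# DS centrality uses.

STATUS_S <- 0L
STATUS_I <- 1L
STATUS_R <- 2L

#' One synchronous SIR/SI step
#'
#' @param status integer vector of per-node states (0 = S, 1 = I, 2 = R).
#' @param x a network or adjacency matrix.
#' @param beta per-contact infection probability.
#' @param mu per-step recovery probability (0 for the SI model).
#' @return the updated status vector. Consumes random numbers from the
#'   current RNG stream; seed the stream for reproducibility.
#' @export
sir_step <- function(status, x, beta, mu) {
  A <- as_adjacency_input(x)
  n <- nrow(A)
  stopifnot(length(status) == n)
  infected <- status == STATUS_I
  m <- as.numeric(A %*% infected)
  p_inf <- 1 - (1 - beta)^m
  new_inf <- status == STATUS_S & runif(n) < p_inf
  recovers <- infected & runif(n) < mu
  status[new_inf] <- STATUS_I
  status[recovers] <- STATUS_R
  status
}

#' Simulate one epidemic trajectory
#'
#' Runs the synchronous SIR/SI dynamics for `params$t` steps from a single
#' infected seed and records the compartment counts after every step
#' (including step 0).
#'
#' @param net a network ([igraph::graph]).
#' @param seed_node seed node (label or 1-based index).
#' @param params [spreading_params()].
#' @param rng_seed optional integer seed; identical seeds give identical
#'   trajectories.
#' @return data frame with columns `step`, `S`, `I`, `R`; `S + I + R = n`
#'   in every row.
#' @export
simulate_sir <- function(net, seed_node, params, rng_seed = NULL) {
  A <- build_adjacency(net)
  params <- as_params(params)
  idx <- resolve_node(net, seed_node, rownames(A))
  run <- function() {
    status <- rep(STATUS_S, nrow(A))
    status[idx] <- STATUS_I
    counts <- matrix(0L, nrow = params$t + 1L, ncol = 3L)
    counts[1L, ] <- tabulate(status + 1L, nbins = 3L)
    for (step in seq_len(params$t)) {
      status <- sir_step(status, A, params$beta, params$mu)
      counts[step + 1L, ] <- tabulate(status + 1L, nbins = 3L)
    }
    counts
  }
  counts <- if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
  data.frame(step = 0:params$t, S = counts[, 1], I = counts[, 2],
             R = counts[, 3])
}

# All replicates propagated jointly: status is an n x n_runs matrix and a
# step is one sparse-dense product plus elementwise draws.
simulate_batch <- function(A, seed_idx, beta, mu, t, n_runs) {
  n <- nrow(A)
  status <- matrix(STATUS_S, n, n_runs)
  status[seed_idx, ] <- STATUS_I
  for (step in seq_len(t)) {
    infected <- status == STATUS_I
    m <- as.matrix(A %*% (infected * 1))
    p_inf <- 1 - (1 - beta)^m
    new_inf <- status == STATUS_S & matrix(runif(n * n_runs), n) < p_inf
    recovers <- infected & matrix(runif(n * n_runs), n) < mu
    status[new_inf] <- STATUS_I
    status[recovers] <- STATUS_R
  }
  colSums(status != STATUS_S)
}

#' Monte-Carlo spreading influence of one node
#'
#' The spreading influence of a node is the expected number of
#' non-susceptible nodes (infected + recovered, the seed included) at step
#' `params$t` when only that node starts infected. Estimated by averaging
#' `n_runs` independent replicates.
#'
#' @param net a network ([igraph::graph]).
#' @param node seed node (label or 1-based index).
#' @param params [spreading_params()].
#' @param n_runs number of replicates.
#' @param rng_seed optional integer master seed.
#' @return list of class `"influence_estimate"` with fields `node`, `t`,
#'   `mean_influence`, `n_runs`, `std_error`.
#' @export
spreading_influence <- function(net, node, params, n_runs = 1000L,
                                rng_seed = NULL) {
  A <- build_adjacency(net)
  params <- as_params(params)
  stopifnot(n_runs >= 1)
  idx <- resolve_node(net, node, rownames(A))
  run <- function() simulate_batch(A, idx, params$beta, params$mu,
                                   params$t, n_runs)
  counts <- if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
  structure(
    list(node = rownames(A)[idx], t = params$t,
         mean_influence = mean(counts), n_runs = n_runs,
         std_error = if (n_runs > 1) sd(counts) / sqrt(n_runs) else NA_real_),
    class = "influence_estimate"
  )
}

#' @export
print.influence_estimate <- function(x, ...) {
  cat(sprintf(
    "Spreading influence of node %s at t = %d: %.4f (SE %.4f, %d runs)\n",
    x$node, x$t, x$mean_influence,
    if (is.na(x$std_error)) NA else x$std_error, x$n_runs))
  invisible(x)
}

# Exact state distribution by outcome enumeration: a map from encoded
# status vectors to probabilities, advanced one synchronous step at a
# time. Per state, infection outcomes (subsets of exposed susceptibles)
# and recovery outcomes (subsets of currently infected) are enumerated
# independently. Exponential in n; guarded.
exact_state_distribution <- function(A, seed_idx, beta, mu, t) {
  n <- nrow(A)
  enc <- function(s) paste(s, collapse = "")
  start <- rep(STATUS_S, n)
  start[seed_idx] <- STATUS_I
  dist <- structure(list(1), names = enc(start))
  states <- structure(list(start), names = enc(start))
  for (step in seq_len(t)) {
    new_dist <- list()
    new_states <- list()
    for (key in names(dist)) {
      prob <- dist[[key]]
      status <- states[[key]]
      inf <- which(status == STATUS_I)
      sus <- which(status == STATUS_S)
      m <- as.numeric(A[sus, inf, drop = FALSE] %*% rep(1, length(inf)))
      exposed <- sus[m > 0]
      p_exp <- 1 - (1 - beta)^m[m > 0]
      n_e <- length(exposed)
      n_i <- length(inf)
      for (imask in seq_len(2^n_e) - 1L) {
        sel_i <- as.logical(bitwAnd(imask, 2^(seq_len(n_e) - 1L)))
        p_i <- prod(p_exp[sel_i]) * prod(1 - p_exp[!sel_i])
        if (p_i == 0) next
        for (rmask in seq_len(2^n_i) - 1L) {
          sel_r <- as.logical(bitwAnd(rmask, 2^(seq_len(n_i) - 1L)))
          p_r <- mu^sum(sel_r) * (1 - mu)^sum(!sel_r)
          if (p_r == 0) next
          ns <- status
          ns[exposed[sel_i]] <- STATUS_I
          ns[inf[sel_r]] <- STATUS_R
          k <- enc(ns)
          new_dist[[k]] <- (if (is.null(new_dist[[k]])) 0 else new_dist[[k]]) +
            prob * p_i * p_r
          new_states[[k]] <- ns
        }
      }
    }
    dist <- new_dist
    states <- new_states
  }
  list(prob = unlist(dist), states = states)
}

check_enumeration_guard <- function(n, t) {
  if (n > 8 || t > 4) {
    stop("exact enumeration is limited to n <= 8 and t <= 4 (got n = ", n,
         ", t = ", t, "); use the Monte-Carlo estimator spreading_influence()")
  }
}

#' Exact expected spreading influence (enumeration oracle)
#'
#' Enumerates every per-contact infection and per-node recovery outcome of
#' the synchronous SIR/SI dynamics and sums probability-weighted influence
#' counts — exact ground truth for validating the Monte-Carlo simulator on
#' small graphs (n <= 8, t <= 4).
#'
#' @param net a network ([igraph::graph]).
#' @param node seed node (label or 1-based index).
#' @param params [spreading_params()].
#' @return exact expected number of non-susceptible nodes at step t.
#' @export
exact_expected_influence <- function(net, node, params) {
  A <- build_adjacency(net)
  params <- as_params(params)
  check_enumeration_guard(nrow(A), params$t)
  idx <- resolve_node(net, node, rownames(A))
  d <- exact_state_distribution(A, idx, params$beta, params$mu, params$t)
  vals <- vapply(names(d$prob),
                 function(k) sum(d$states[[k]] != STATUS_S), 1)
  sum(d$prob * vals)
}

#' Exact per-node infection probabilities (enumeration oracle)
#'
#' For every node, the exact probability of being infected during steps
#' 1..t given `node` starts infected: 1 - P(still susceptible at t) for
#' non-seed nodes, and 0 for the seed itself (it is never re-susceptible).
#' The linearized [infection_probabilities()] overestimates every entry.
#'
#' @inheritParams exact_expected_influence
#' @return named numeric probability vector.
#' @export
exact_infection_probabilities <- function(net, node, params) {
  A <- build_adjacency(net)
  params <- as_params(params)
  check_enumeration_guard(nrow(A), params$t)
  idx <- resolve_node(net, node, rownames(A))
  d <- exact_state_distribution(A, idx, params$beta, params$mu, params$t)
  p_sus <- rowSums(vapply(names(d$prob),
                          function(k) d$prob[[k]] * (d$states[[k]] == STATUS_S),
                          numeric(nrow(A))))
  out <- 1 - p_sus
  out[idx] <- 0
  structure(out, names = rownames(A))
}
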