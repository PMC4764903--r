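# Ranking accuracy: Kendall's tau between centrality scores and simulated
# spreading influence, and the benchmark experiment sweeping the spreading
# rate over a grid with a shared influence vector per rate.

#' Kendall's tau rank correlation
#'
#' The tau-a form: (2 / (n (n - 1))) * sum_{i<j} sgn(y_i - y_j) *
#' sgn(z_i - z_j). Tied pairs contribute 0, so the value reaches +/-1 only
#' on tie-free perfectly concordant/discordant lists; a constant vector
#' yields 0. `variant = "b"` delegates to [stats::cor()] for the
#' tie-corrected tau-b.
#'
#' @param y,z numeric vectors of equal length (n >= 2).
#' @param variant `"a"` (default) or `"b"`.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(y, z, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(y) != length(z)) stop("'y' and 'z' must have equal length")
  n <- length(y)
  if (n < 2) stop("need at least two observations")
  if (variant == "b") return(stats::cor(y, z, method = "kendall"))
  sy <- sign(outer(y, y, `-`))
  sz <- sign(outer(z, z, `-`))
  sum(sy[upper.tri(sy)] * sz[upper.tri(sz)]) * 2 / (n * (n - 1))
}

#' Spreading influence of every node
#'
#' Runs [spreading_influence()] with every node as seed under one master
#' seed (per-node sub-seeds are drawn up front, so the result does not
#' depend on evaluation order).
#'
#' @param net a connected network.
#' @param params [spreading_params()].
#' @param n_runs replicates per seed node.
#' @param rng_seed integer master seed.
#' @return named numeric vector of mean influences.
#' @export
influence_vector <- function(net, params, n_runs = 1000L, rng_seed = 1L) {
  A <- build_adjacency(net)
  n <- nrow(A)
  params <- as_params(params)
  sub_seeds <- withr::with_seed(rng_seed, sample.int(.Machine$integer.max, n))
  vals <- vapply(seq_len(n), function(i) {
    withr::with_seed(sub_seeds[i],
      mean(simulate_batch(A, i, params$beta, params$mu, params$t, n_runs)))
  }, 1)
  structure(vals, names = rownames(A))
}

#' Centrality-vs-influence accuracy experiment
#'
#' For each spreading rate in `beta_grid`: estimate the influence of every
#' node by Monte Carlo (one shared influence vector per rate), compute each
#' requested centrality (the DS centrality uses the same beta, mu and t as
#' the simulation), and record Kendall's tau-a between the two rankings.
#' When all influences are tied (e.g. beta = 0) tau is 0 by construction
#' and the row is flagged degenerate.
#'
#' @param net a connected network.
#' @param beta_grid numeric vector of spreading rates.
#' @param mu recovery rate shared by simulation and DS centrality.
#' @param t time horizon shared by simulation and DS centrality.
#' @param methods subset of `c("ds", "degree", "kshell", "eigenvector")`.
#' @param n_runs Monte-Carlo replicates per seed node.
#' @param rng_seed integer master seed.
#' @param network_id identifier recorded in the result metadata.
#' @return data frame with columns `beta`, `method`, `tau`, `degenerate`
#'   and a `"metadata"` attribute (mu, t, n_runs, rng_seed, network_id).
#' @export
accuracy_experiment <- function(net, beta_grid = seq(0.01, 0.10, by = 0.01),
                                mu = 1, t = 5L,
                                methods = c("ds", "degree", "kshell",
                                            "eigenvector"),
                                n_runs = 500L, rng_seed = 1L,
                                network_id = "network") {
  methods <- match.arg(methods, several.ok = TRUE)
  # static centralities do not depend on beta; compute once
  static <- list()
  for (m in setdiff(methods, "ds")) static[[m]] <- centrality(net, m)
  beta_seeds <- withr::with_seed(rng_seed,
    sample.int(.Machine$integer.max, length(beta_grid)))
  rows <- vector("list", length(beta_grid) * length(methods))
  k <- 0L
  for (b in seq_along(beta_grid)) {
    beta <- beta_grid[[b]]
    params <- spreading_params(beta, mu, t)
    infl <- influence_vector(net, params, n_runs, beta_seeds[b])
    degenerate <- max(infl) == min(infl)
    for (m in methods) {
      scores <- if (m == "ds") ds_centrality(net, params) else static[[m]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        beta = beta, method = m,
        tau = kendall_tau(infl, as.numeric(scores)[match(names(infl),
                                                         names(scores))]),
        degenerate = degenerate
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(mu = mu, t = t, n_runs = n_runs,
                                rng_seed = rng_seed, network_id = network_id)
  out
}
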