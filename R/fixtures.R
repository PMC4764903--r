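# Deterministic toy graphs and seeded random-network generators; every test
# and experiment in the package runs on these, no downloads required.

relabel_canonical <- function(g) {
  n <- igraph::vcount(g)
  igraph::V(g)$name <- as.character(seq_len(n) - 1L)
  g
}

#' Canonical toy graphs
#'
#' Hand-analyzable labeled graphs with 0-based character labels:
#' \describe{
#'   \item{path}{path on `n` nodes, edges (0,1), (1,2), ...}
#'   \item{cycle}{cycle on `n` nodes}
#'   \item{complete}{complete graph K_n}
#'   \item{star}{one center (label "0") with `n` leaves, n + 1 nodes total}
#'   \item{triangle_pendant}{K3 on nodes 0,1,2 plus a pendant node 3
#'     attached to node 0 (degrees 3,2,2,1)}
#' }
#'
#' @param family one of `"path"`, `"star"`, `"cycle"`, `"complete"`,
#'   `"triangle_pendant"`.
#' @param n size parameter (leaf count for `star`; ignored for
#'   `triangle_pendant`).
#' @return a network ([igraph::graph]).
#' @export
toy_graph <- function(family = c("path", "star", "cycle", "complete",
                                 "triangle_pendant"), n = 3L) {
  family <- match.arg(family)
  g <- switch(family,
    path = {
      stopifnot(n >= 2)
      igraph::make_ring(n, circular = FALSE)
    },
    cycle = {
      stopifnot(n >= 3)
      igraph::make_ring(n, circular = TRUE)
    },
    complete = {
      stopifnot(n >= 2)
      igraph::make_full_graph(n)
    },
    star = {
      stopifnot(n >= 1)
      igraph::make_star(n + 1L, mode = "undirected", center = 1L)
    },
    triangle_pendant = {
      igraph::graph_from_edgelist(
        cbind(c("0", "0", "1", "0"), c("1", "2", "2", "3")),
        directed = FALSE)
    }
  )
  if (is.null(igraph::V(g)$name)) g <- relabel_canonical(g)
  make_network(igraph::as_edgelist(g, names = TRUE))
}

#' Seeded random connected networks
#'
#' Erdos-Renyi G(n, p), Barabasi-Albert preferential attachment and
#' Watts-Strogatz small-world generators, resampled (up to `max_retries`
#' times) until connected; bit-reproducible for a given `rng_seed`.
#'
#' @param model `"er"`, `"ba"` or `"ws"`.
#' @param n node count.
#' @param p edge probability (er) or rewiring probability (ws).
#' @param m edges attached per new node (ba).
#' @param k even neighbourhood degree of the ring lattice (ws).
#' @param rng_seed integer seed.
#' @param max_retries resampling budget before giving up on connectivity.
#' @return a connected network with 0-based canonical labels.
#' @export
random_graph <- function(model = c("er", "ba", "ws"), n, p = NULL, m = NULL,
                         k = NULL, rng_seed = 1L, max_retries = 100L) {
  model <- match.arg(model)
  withr::with_seed(rng_seed, {
    for (try in seq_len(max_retries)) {
      g <- switch(model,
        er = {
          stopifnot(!is.null(p))
          igraph::sample_gnp(n, p)
        },
        ba = {
          stopifnot(!is.null(m))
          igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
        },
        ws = {
          stopifnot(!is.null(k), k %% 2 == 0, !is.null(p))
          igraph::sample_smallworld(1, n, k / 2, p)
        }
      )
      g <- igraph::simplify(g)
      if (igraph::is_connected(g)) {
        g <- relabel_canonical(g)
        return(make_network(igraph::as_edgelist(g, names = TRUE)))
      }
    }
  })
  stop("could not generate a connected '", model, "' graph in ",
       max_retries, " attempts; adjust the parameters")
}
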