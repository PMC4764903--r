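#' @importFrom stats runif sd
NULL

# Deterministic node ordering: numeric sort when every label parses as an
# integer, locale-independent lexicographic sort otherwise.
sort_labels <- function(labels) {
  labels <- unique(as.character(labels))
  if (length(labels) && all(grepl("^-?[0-9]+$", labels))) {
    labels[order(as.numeric(labels))]
  } else {
    sort(labels, method = "radix")
  }
}

#' Build a network from an edge table
#'
#' Constructs the canonical undirected simple network used throughout the
#' package: duplicate edges (including reversed duplicates) are collapsed,
#' self-loops are an error, and vertices are indexed in a deterministic
#' order (numeric when all labels are integers, lexicographic otherwise).
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param isolated character vector of additional degree-zero node labels.
#' @return an [igraph::graph] object with named vertices.
#' @export
make_network <- function(edges, isolated = character()) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2) {
    stop("'edges' must have exactly two columns")
  }
  mode(edges) <- "character"
  if (nrow(edges)) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      stop("self-loops are not allowed (node ", edges[which(loops)[1], 1], ")")
    }
    # canonical unordered pair, then collapse duplicates
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- cbind(a[keep], b[keep])
  }
  labels <- sort_labels(c(edges, isolated))
  if (!length(labels)) stop("empty network")
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labels, stringsAsFactors = FALSE)
  )
  g
}

#' Read an undirected network from a plain-text edge list
#'
#' One edge per line, two node labels separated by whitespace or commas
#' (or an explicit `delimiter`). Lines starting with `comment` and blank
#' lines are skipped; trailing comments are stripped. Duplicate and
#' reversed-duplicate edges are collapsed silently; a self-loop or a line
#' without exactly two tokens is an error naming the line number.
#'
#' @param path path to the edge-list file.
#' @param delimiter optional single delimiter string; default splits on any
#'   run of whitespace and/or commas.
#' @param comment comment prefix, default `"#"`.
#' @return an [igraph::graph] object (see [make_network()]).
#' @export
read_edge_list <- function(path, delimiter = NULL, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (nzchar(comment)) line <- sub(paste0(comment, ".*$"), "", line, fixed = FALSE)
    line <- trimws(line)
    if (!nzchar(line)) next
    tokens <- if (is.null(delimiter)) {
      strsplit(line, "[,[:space:]]+")[[1]]
    } else {
      trimws(strsplit(line, delimiter, fixed = TRUE)[[1]])
    }
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != 2) {
      stop("parse error at line ", i, ": expected two node labels, got ",
           length(tokens))
    }
    if (tokens[1] == tokens[2]) {
      stop("self-loop at line ", i, ": node '", tokens[1], "'")
    }
    out[[i]] <- tokens
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no edges found in ", path)
  make_network(do.call(rbind, out))
}

#' Write a network as a plain-text edge list
#'
#' @param net a network ([igraph::graph]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Adjacency matrix of a network
#'
#' Binary, symmetric, zero-diagonal sparse matrix with dimnames set to the
#' node labels; row i sums to the degree of node i.
#'
#' @param net a network ([igraph::graph]).
#' @return a sparse symmetric 0/1 `Matrix` with zero diagonal.
#' @export
build_adjacency <- function(net) {
  A <- igraph::as_adjacency_matrix(net, type = "both", sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  A@x[A@x != 0] <- 1
  A
}

# Accept either a network or an adjacency matrix in matrix-level operations.
as_adjacency_input <- function(x) {
  if (igraph::is_igraph(x)) return(build_adjacency(x))
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  if (!methods::is(x, "Matrix")) stop("expected a network or adjacency matrix")
  if (nrow(x) != ncol(x)) stop("adjacency matrix must be square")
  x
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; ties between equal-size
#' components are broken in favour of the component containing the smallest
#' node label (in canonical label order).
#'
#' @param net a network ([igraph::graph]).
#' @return the induced subgraph, vertex order preserved.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # vertex order is canonical, so the first vertex in a tied component
    # carries its smallest label
    first_vertex <- vapply(best, function(cc) min(which(comp$membership == cc)), 1L)
    best <- best[which.min(first_vertex)]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

# Largest adjacency eigenvalue. Dense symmetric solver up to n = 3000,
# shifted power iteration (A + I, primitive on connected graphs) above.
lambda1 <- function(A, tol = 1e-12, max_iter = 100000L) {
  A <- as_adjacency_input(A)
  n <- nrow(A)
  if (n <= 3000) {
    return(eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values[1])
  }
  v <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v
    w <- w / sum(w)
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  sum(v * as.numeric(A %*% v)) / sum(v * v)
}

#' Summary statistics of a network
#'
#' Node count n, edge count e, average degree 2e/n, the largest adjacency
#' eigenvalue lambda1 and its reciprocal 1/lambda1 — the epidemic threshold
#' of SIR dynamics on the network.
#'
#' @param net a network ([igraph::graph]).
#' @return a list of class `"network_summary"` with fields `n`, `e`,
#'   `avg_degree`, `lambda1`, `inv_lambda1`.
#' @export
network_summary <- function(net) {
  if (!igraph::is_connected(net)) {
    warning("network is disconnected; summary computed on the input as given")
  }
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  l1 <- lambda1(build_adjacency(net))
  structure(
    list(n = n, e = e, avg_degree = 2 * e / n,
         lambda1 = l1, inv_lambda1 = 1 / l1),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "Network summary: n = %d, e = %d, <k> = %.4f, lambda1 = %.6f, 1/lambda1 = %.6f\n",
    x$n, x$e, x$avg_degree, x$lambda1, x$inv_lambda1))
  invisible(x)
}
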