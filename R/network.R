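#' Coupling graphs
#'
#' A `coupling_graph` is a nonnegative weight matrix with zero diagonal;
#' entry `weights[i, j]` is the strength of the diffusive connection from
#' unit `j` into unit `i` (row = receiver).  On construction the graph is
#' tagged `symmetric` and `balanced`; a network is *balanced* when every
#' node's total incoming weight equals its total outgoing weight, the
#' structural property that makes all coupling terms cancel in the
#' population sum.  Any symmetric network is balanced.
#'
#' @param weights square numeric matrix, nonnegative, zero diagonal.
#' @param tol tolerance used for the symmetric/balanced tags.
#' @return an object of class `coupling_graph`.
#' @export
coupling_graph <- function(weights, tol = 1e-9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n || n < 1L) {
    abort_invalid("`weights` must be a square matrix.")
  }
  if (!all(is.finite(weights)) || any(weights < 0)) {
    abort_invalid("`weights` must be finite and nonnegative.")
  }
  if (any(diag(weights) != 0)) {
    abort_invalid("self-coupling is not allowed: the diagonal must be zero.")
  }
  g <- structure(
    list(n_nodes = n, weights = unname(weights),
         symmetric = isTRUE(all.equal(weights, t(weights), tolerance = 0,
                                      check.attributes = FALSE)) ||
           max(abs(weights - t(weights))) <= tol,
         balanced = NA),
    class = "coupling_graph")
  g$balanced <- is_balanced(g, tol = tol)
  g
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("<coupling_graph> ", x$n_nodes, " nodes, ",
      sum(x$weights > 0), " directed edges",
      if (x$symmetric) ", symmetric", if (x$balanced) ", balanced",
      "\n", sep = "")
  invisible(x)
}

#' All-to-all network with identical couplings
#'
#' Every ordered pair of distinct units is connected with the same strength
#' `k`.  Such a network is symmetric, therefore balanced, and admits an
#' exactly equivalent quorum-sensing star form ([to_quorum_star()]).
#'
#' @param n number of units (>= 2).
#' @param k positive coupling strength per connection.
#' @return a [coupling_graph()].
#' @export
build_all_to_all <- function(n, k) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort_invalid("`n` must be an integer >= 2.")
  check_number(k, "k", min = 0, strict_min = TRUE)
  w <- matrix(k, n, n)
  diag(w) <- 0
  coupling_graph(w)
}

#' Probabilistic symmetric network
#'
#' Each unordered pair of units is independently connected with probability
#' `p`; a connected pair gets weight `k` in both directions, so the result
#' is always symmetric (hence balanced).  `p = 1` reproduces the all-to-all
#' network and `p = 0` the empty one.  Disconnected realizations are kept
#' (globally synchronized behavior then cannot be expected) but trigger a
#' warning.
#'
#' @param n number of units (>= 2).
#' @param p connection probability in `[0, 1]`.
#' @param k positive coupling strength.
#' @param seed integer seed; the same seed yields the same graph.
#' @return a [coupling_graph()].
#' @export
build_probabilistic <- function(n, p, k, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort_invalid("`n` must be an integer >= 2.")
  check_number(p, "p", min = 0)
  if (p > 1) abort_invalid("`p` must be <= 1.")
  check_number(k, "k", min = 0, strict_min = TRUE)
  w <- matrix(0, n, n)
  with_preserved_seed(seed, {
    idx <- which(upper.tri(w))
    w[idx] <- k * (runif(length(idx)) < p)
  })
  w <- w + t(w)
  g <- coupling_graph(w)
  if (!graph_is_connected(g)) {
    warn("probabilistic graph is not connected; disconnected components cannot synchronize globally.",
         class = "oscnet_disconnected_graph")
  }
  g
}

graph_is_connected <- function(graph) {
  adj <- graph$weights > 0
  reach <- logical(graph$n_nodes)
  reach[1L] <- TRUE
  repeat {
    new <- reach | as.logical((adj | t(adj)) %*% reach > 0)
    if (all(new == reach)) break
    reach <- new
  }
  all(reach)
}

#' Is a network balanced?
#'
#' A node is balanced when its incoming weight sum equals its outgoing
#' weight sum; the network is balanced when every node is.  With the
#' row-receives convention this compares row sums with column sums.
#'
#' @param graph a [coupling_graph()].
#' @param tol absolute tolerance on the row/column sum difference.
#' @return logical.
#' @export
is_balanced <- function(graph, tol = 1e-9) {
  stopifnot(inherits(graph, "coupling_graph"))
  check_number(tol, "tol", min = 0)
  all(abs(rowSums(graph$weights) - colSums(graph$weights)) <= tol)
}

#' Diffusive coupling term
#'
#' For each unit `i` returns \eqn{\sum_j w_{ij} (x_j - x_i)} on the masked
#' components (all other components zero).  The term vanishes on the
#' synchronization subspace (identical states), depends only on state
#' differences, and for any balanced graph its sum over nodes is exactly
#' the zero vector -- the algebraic cancellation that isolates the
#' population mean from the coupling.
#'
#' @param graph a [coupling_graph()] or `quorum_star`.
#' @param states N x dim state matrix (rows = units).
#' @param mask logical vector over components; defaults to first component.
#' @return N x dim matrix of coupling contributions.
#' @export
coupling_term <- function(graph, states, mask = NULL) {
  UseMethod("coupling_term")
}

#' @export
coupling_term.coupling_graph <- function(graph, states, mask = NULL) {
  states <- as.matrix(states)
  if (nrow(states) != graph$n_nodes) {
    abort_invalid("`states` must have one row per graph node.")
  }
  mask <- mask %||% c(TRUE, rep(FALSE, ncol(states) - 1L))
  out <- matrix(0, nrow(states), ncol(states))
  cols <- which(mask)
  xs <- states[, cols, drop = FALSE]
  out[, cols] <- graph$weights %*% xs - rowSums(graph$weights) * xs
  out
}

#' Quorum-sensing star reformulation
#'
#' An all-to-all network of `n` units with identical coupling `k` can be
#' rewritten as a star: each unit feels a local damping `-n k x_i` plus an
#' attraction `n k` toward the common mean signal \eqn{\bar x}, since
#' \eqn{k \sum_j (x_j - x_i) = n k (\bar x - x_i)}.  This is the
#' quorum-sensing implementation of all-to-all coupling -- each cell only
#' measures one shared environmental mean -- and it uses `n` connections
#' instead of `n^2`.  Simulating the star form with the same noise stream
#' reproduces the all-to-all updates to floating-point accuracy.
#'
#' @param n number of units (>= 2).
#' @param k positive coupling strength of the underlying all-to-all network.
#' @return an object of class `quorum_star` usable wherever a graph is
#'   (e.g. in [euler_maruyama()] or [coupling_term()]).
#' @export
to_quorum_star <- function(n, k) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort_invalid("`n` must be an integer >= 2.")
  check_number(k, "k", min = 0, strict_min = TRUE)
  structure(list(n_nodes = n, k = k, damping = n * k,
                 n_connections = n, symmetric = TRUE, balanced = TRUE),
            class = c("quorum_star"))
}

#' @export
print.quorum_star <- function(x, ...) {
  cat("<quorum_star> ", x$n_nodes, " nodes, damping ", x$damping,
      ", mean-field coupling ", x$k, "\n", sep = "")
  invisible(x)
}

#' @export
coupling_term.quorum_star <- function(graph, states, mask = NULL) {
  states <- as.matrix(states)
  if (nrow(states) != graph$n_nodes) {
    abort_invalid("`states` must have one row per graph node.")
  }
  mask <- mask %||% c(TRUE, rep(FALSE, ncol(states) - 1L))
  out <- matrix(0, nrow(states), ncol(states))
  cols <- which(mask)
  xs <- states[, cols, drop = FALSE]
  means <- colMeans(xs)
  out[, cols] <- graph$damping *
    sweep(-xs, 2L, means, "+")  # n k (xbar - x_i)
  out
}

#' Edge-list serialization
#'
#' Writes/reads a graph as a plain-text edge list with columns
#' `source`, `target`, `weight` (`target` receives).  Nodes with no edges
#' are preserved through the `n_nodes` attribute column written in the
#' header comment-free way: the maximum node index is taken from the data,
#' so pass `n_nodes` on read for graphs with isolated nodes.
#'
#' @param graph a [coupling_graph()].
#' @param path file path.
#' @return `graph_to_edgelist` returns a tibble (invisibly when writing).
#' @export
graph_to_edgelist <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "coupling_graph"))
  idx <- which(graph$weights > 0, arr.ind = TRUE)
  el <- tibble(source = idx[, 2L], target = idx[, 1L],
               weight = graph$weights[idx])
  el <- dplyr::arrange(el, .data$source, .data$target)
  if (!is.null(path)) {
    write.csv(el, path, row.names = FALSE)
    return(invisible(el))
  }
  el
}

#' @param edgelist data frame with columns `source`, `target`, `weight`, or
#'   a path to a CSV holding one.
#' @param n_nodes number of nodes; defaults to the largest index present.
#' @rdname graph_to_edgelist
#' @export
graph_from_edgelist <- function(edgelist, n_nodes = NULL) {
  if (is.character(edgelist)) edgelist <- read.csv(edgelist)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(edgelist))) {
    abort_invalid("edge list needs columns source, target, weight.")
  }
  n <- n_nodes %||% max(edgelist$source, edgelist$target)
  w <- matrix(0, n, n)
  w[cbind(edgelist$target, edgelist$source)] <- edgelist$weight
  coupling_graph(w)
}

graph_digest <- function(graph) {
  if (is.null(graph)) return("uncoupled")
  if (inherits(graph, "quorum_star")) {
    return(sprintf("quorum_star(n=%d,k=%g)", graph$n_nodes, graph$k))
  }
  rlang::hash(graph$weights)
}
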