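# Reference message-passing engine.  This is the general formulation the
# production layers specialize: per-node states are updated synchronously
# from aggregated neighbor messages until the per-node state change drops
# below a tolerance or an iteration cap is hit.  It is deliberately simple
# (plain loops over an adjacency list) so it can serve as a brute-force
# oracle for the learned layers.

#' Message-passing configuration
#'
#' @param aggregation `"mean"` (coefficient `a = 1/|Ne|`, the average
#'   aggregator) or `"sum"` (`a = 1`).
#' @param tolerance Convergence threshold on the Euclidean per-node state
#'   change (default 1e-4).
#' @param max_iterations Iteration cap `k_max` (default 10).
#' @return An `mp_config` list.
#' @export
mp_config <- function(aggregation = c("mean", "sum"), tolerance = 1e-4,
                      max_iterations = 10L) {
  aggregation <- match.arg(aggregation)
  stopifnot(tolerance > 0, max_iterations >= 1L)
  structure(list(aggregation = aggregation, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "mp_config")
}

#' Construct a message from a source node
#'
#' The message from neighbor `j` to node `i` is the concatenation of the
#' source state with the edge label, `(s_j, e_ij)`.
#'
#' @param source_state Numeric state vector of the source node.
#' @param edge_label Numeric edge label (possibly length 0).
#' @return Numeric vector of length `|s| + |e|`.
#' @export
mp_message <- function(source_state, edge_label = numeric(0)) {
  stopifnot(all(is.finite(source_state)),
            all(is.finite(edge_label)) || length(edge_label) == 0L)
  c(source_state, edge_label)
}

#' Aggregate neighbor messages
#'
#' Computes `a * sum(messages)` with `a = 1/|Ne|` (mean mode) or `a = 1`
#' (sum mode).  An empty neighborhood returns a zero vector of the given
#' length: the mean form divides by `|Ne|`, which is undefined at zero, so
#' isolated nodes receive a null message by convention.
#'
#' @param messages List of equal-length numeric vectors (possibly empty).
#' @param config An [mp_config()].
#' @param message_length Length of the zero vector returned for an empty
#'   neighborhood.
#' @return Aggregated message vector.
#' @export
mp_aggregate <- function(messages, config = mp_config(),
                         message_length = NULL) {
  if (!length(messages)) {
    if (is.null(message_length)) {
      stop("empty neighborhood needs an explicit message_length",
           call. = FALSE)
    }
    return(numeric(message_length))
  }
  len <- lengths(messages)
  if (length(unique(len)) != 1L) {
    stop("messages must all have the same length", call. = FALSE)
  }
  total <- Reduce(`+`, messages)
  if (config$aggregation == "mean") total / length(messages) else total
}

#' Run synchronous message passing to convergence
#'
#' Starting from `s_i^0 = l_i`, every node is updated simultaneously at each
#' step: `s_i^k = F(s_i^{k-1}, a * sum_j (s_j^{k-1}, e_ij))`.  Iteration
#' stops at the first `k` with `max_i ||s_i^k - s_i^{k-1}||_2 < tolerance`,
#' or at `max_iterations`.
#'
#' @param n_nodes Number of nodes.
#' @param edges Two-column matrix of undirected edges (1-based node
#'   indices); both directions exchange messages.
#' @param init_labels List (length `n_nodes`) of initial state vectors, or
#'   a numeric matrix with one row per node.
#' @param update_fn `F(previous_state, aggregated_message)` returning the
#'   new state (same length as the previous state).
#' @param config An [mp_config()].
#' @param edge_labels Optional list of per-edge label vectors (one per row
#'   of `edges`; the same label serves both directions).
#' @return A `graph_state`: list with `states` (list of final per-node
#'   vectors), `iterations` (stopping step), and `converged`.
#' @export
mp_propagate <- function(n_nodes, edges, init_labels, update_fn,
                         config = mp_config(), edge_labels = NULL) {
  if (is.matrix(init_labels)) {
    init_labels <- lapply(seq_len(nrow(init_labels)),
                          function(i) init_labels[i, ])
  }
  stopifnot(length(init_labels) == n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2L)
  nbr <- vector("list", n_nodes)
  nbr_edge <- vector("list", n_nodes)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      nbr[[i]] <- c(nbr[[i]], j); nbr_edge[[i]] <- c(nbr_edge[[i]], e)
      nbr[[j]] <- c(nbr[[j]], i); nbr_edge[[j]] <- c(nbr_edge[[j]], e)
    }
  }
  elab <- function(e) {
    if (is.null(edge_labels)) numeric(0) else edge_labels[[e]]
  }
  states <- init_labels
  msg_len <- length(states[[1]]) +
    (if (is.null(edge_labels)) 0L else length(edge_labels[[1]]))
  converged <- FALSE
  k <- 0L
  while (k < config$max_iterations) {
    k <- k + 1L
    new_states <- vector("list", n_nodes)
    for (i in seq_len(n_nodes)) {
      msgs <- if (length(nbr[[i]])) {
        lapply(seq_along(nbr[[i]]), function(t) {
          mp_message(states[[nbr[[i]][t]]], elab(nbr_edge[[i]][t]))
        })
      } else list()
      agg <- mp_aggregate(msgs, config, message_length = msg_len)
      s <- update_fn(states[[i]], agg)
      if (any(!is.finite(s))) {
        stop(sprintf("update produced a non-finite state at node %d, iteration %d",
                     i, k), call. = FALSE)
      }
      if (length(s) != length(states[[i]])) {
        stop(sprintf("update changed the state dimension at node %d", i),
             call. = FALSE)
      }
      new_states[[i]] <- s
    }
    delta <- max(vapply(seq_len(n_nodes), function(i) {
      sqrt(sum((new_states[[i]] - states[[i]])^2))
    }, numeric(1)))
    states <- new_states
    if (delta < config$tolerance) { converged <- TRUE; break }
  }
  structure(list(states = states, iterations = k, converged = converged),
            class = "graph_state")
}
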