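# Explicit network state for the stochastic simulation: a simple undirected
# graph with per-node immutable type (A/B) and mutable epidemic state (S/I).
# Edges are stored as a 2-column 1-based integer matrix with the smaller id
# first; types are 1 (A) / 2 (B); states are 0 (S) / 1 (I).

#' Construct a network state
#'
#' @param edges 2-column integer matrix of undirected edges (1-based node
#'   ids, no self-loops, no duplicates).
#' @param type integer vector, 1 = type A, 2 = type B (or characters
#'   "A"/"B").
#' @param state integer vector, 0 = susceptible, 1 = infected (or "S"/"I");
#'   may be `NULL` for a network whose epidemic states are not yet assigned.
#' @param n_nodes node count; inferred from `length(type)` if missing.
#' @return object of class `sis_network`.
#' @export
network_state <- function(edges, type, state = NULL, n_nodes = length(type)) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (is.character(type)) type <- match(type, c("A", "B"))
  type <- as.integer(type)
  if (!is.null(state)) {
    if (is.character(state)) state <- match(state, c("S", "I")) - 1L
    state <- as.integer(state)
    stopifnot(length(state) == n_nodes, all(state %in% 0:1))
  }
  stopifnot(length(type) == n_nodes, all(type %in% 1:2))
  if (nrow(edges)) {
    stopifnot(all(edges >= 1L), all(edges <= n_nodes),
              all(edges[, 1] != edges[, 2]))
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    key <- (edges[, 1] - 1) * n_nodes + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    edges <- edges[order(key), , drop = FALSE]
  }
  structure(list(edges = edges, type = type, state = state,
                 n_nodes = as.integer(n_nodes)),
            class = "sis_network")
}

#' @export
print.sis_network <- function(x, ...) {
  cat(sprintf("sis_network: %d nodes (%d type A), %d edges",
              x$n_nodes, sum(x$type == 1L), nrow(x$edges)))
  if (!is.null(x$state))
    cat(sprintf(", %d infected", sum(x$state)))
  cat("\n")
  invisible(x)
}

#' Erdos-Renyi G(N, K) network
#'
#' Draws a graph uniformly among all simple graphs with `n_nodes` nodes and
#' exactly `n_links` edges.  Node types and epidemic states are left unset.
#'
#' @param n_nodes,n_links node and edge counts.
#' @return a [network_state()] with `type` initialized to all A and `state`
#'   unset.
#' @export
generate_er_network <- function(n_nodes, n_links) {
  if (n_links > n_nodes * (n_nodes - 1) / 2)
    stop("n_links exceeds the number of possible edges", call. = FALSE)
  g <- igraph::sample_gnm(n_nodes, n_links)
  edges <- igraph::as_edgelist(g, names = FALSE)
  network_state(edges, type = rep(1L, n_nodes), state = NULL,
                n_nodes = n_nodes)
}

#' Assign types and epidemic states uniformly at random
#'
#' Exactly `round(n_nodes * p_a)` nodes become type A and exactly
#' `round(n_nodes * initial_prevalence)` nodes become infected, each chosen
#' uniformly at random and independently of one another (and hence of
#' degree).
#'
#' @param net a [network_state()].
#' @param p_a fraction of type-A nodes.
#' @param initial_prevalence initial infected fraction.
#' @return the network with `type` and `state` set.
#' @export
assign_initial_condition <- function(net, p_a, initial_prevalence) {
  stopifnot(p_a >= 0, p_a <= 1,
            initial_prevalence >= 0, initial_prevalence <= 1)
  n <- net$n_nodes
  n_a <- round(n * p_a)
  n_i <- round(n * initial_prevalence)
  type <- rep(2L, n)
  type[sample.int(n, n_a)] <- 1L
  state <- rep(0L, n)
  state[sample.int(n, n_i)] <- 1L
  net$type <- type
  net$state <- state
  net
}

#' Reset a stationary network to the adapted-restart initial condition
#'
#' Keeps the self-organized link pattern and node types, wipes all epidemic
#' states, and infects exactly `n_infected` uniformly chosen nodes.  This is
#' the protocol used to probe the invasion threshold of an adapted network.
#'
#' @param stationary_net a [network_state()] (typically the final network of
#'   [run_to_stationarity()]).
#' @param n_infected number of initially infected nodes (default 20).
#' @return the restart [network_state()].
#' @export
adapted_restart_state <- function(stationary_net, n_infected = 20) {
  n <- stationary_net$n_nodes
  if (n_infected > n) stop("n_infected exceeds the node count", call. = FALSE)
  state <- rep(0L, n)
  state[sample.int(n, n_infected)] <- 1L
  stationary_net$state <- state
  stationary_net
}

#' Per-type degree statistics
#'
#' @param net a [network_state()].
#' @return list with per-type mean degrees `k_a`, `k_b`, the `ratio`
#'   `k_b / k_a` (NA when a type is empty), the overall `k_mean`, and the
#'   per-type degree tables `hist_a`, `hist_b`.
#' @export
degree_stats <- function(net) {
  deg <- tabulate(c(net$edges), nbins = net$n_nodes)
  a <- net$type == 1L
  k_a <- if (any(a)) mean(deg[a]) else NA_real_
  k_b <- if (any(!a)) mean(deg[!a]) else NA_real_
  list(k_a = k_a, k_b = k_b,
       ratio = if (is.na(k_a) || is.na(k_b) || k_a == 0) NA_real_
               else k_b / k_a,
       k_mean = mean(deg),
       hist_a = table(deg[a]), hist_b = table(deg[!a]),
       degrees = deg)
}

#' Execute a single rewiring event
#'
#' The susceptible end of `si_link` cuts the link to its infected neighbour
#' and reconnects to a node drawn uniformly from the eligible targets:
#' susceptible, not itself, and not already a neighbour (the graph stays
#' simple).  If no eligible target exists the event is a no-op and the link
#' is left intact.
#'
#' @param net a [network_state()] with states assigned.
#' @param si_link integer pair `(node, node)` currently linking one
#'   susceptible and one infected node.
#' @return the updated [network_state()]; attribute `rewired` says whether
#'   the event took place, attribute `new_target` the chosen partner.
#' @export
rewire_event <- function(net, si_link) {
  u <- si_link[1]; v <- si_link[2]
  e <- net$edges
  hit <- which((e[, 1] == min(u, v)) & (e[, 2] == max(u, v)))
  if (!length(hit)) stop("si_link is not an edge", call. = FALSE)
  st <- net$state[c(u, v)]
  if (sum(st) != 1L)
    stop("internal consistency error: si_link does not join one S and one ",
         "I node", call. = FALSE)
  s_node <- if (st[1] == 0L) u else v
  nbrs <- c(e[e[, 1] == s_node, 2], e[e[, 2] == s_node, 1])
  eligible <- setdiff(which(net$state == 0L), c(s_node, nbrs))
  if (!length(eligible)) {
    attr(net, "rewired") <- FALSE
    return(net)
  }
  target <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  e[hit, ] <- c(min(s_node, target), max(s_node, target))
  net$edges <- e
  attr(net, "rewired") <- TRUE
  attr(net, "new_target") <- target
  net
}
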