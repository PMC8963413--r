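#' Network parameters
#'
#' Parameters of the agent interaction network: a Barabasi-Albert (BA)
#' scale-free graph whose highest-degree nodes act as opinion leaders.
#' Preferential attachment mimics the social fact that people tend to
#' interact with already well-connected, influential individuals.
#'
#' @param n_agents total number of agents (nodes), `N`.
#' @param m_attach edges added per new node during preferential attachment.
#'   The growth starts from a complete seed graph on `m_attach + 1` nodes, so
#'   `n_agents >= m_attach + 1` is required.
#' @param leader_fraction proportion of nodes, taken from the top of the
#'   degree ranking, designated opinion leaders. The default 0.05 marks the
#'   top 5 percent best-connected nodes.
#' @return an object of class `network_params`.
#' @examples
#' network_params(n_agents = 1000)
#' @export
network_params <- function(n_agents = 1000, m_attach = 3, leader_fraction = 0.05) {
  n_agents <- check_count(n_agents, "n_agents", min = 1L)
  m_attach <- check_count(m_attach, "m_attach", min = 1L)
  check_prob(leader_fraction, "leader_fraction")
  if (n_agents < m_attach + 1L) {
    abort_bad_arg("`n_agents` must be at least `m_attach` + 1 (the seed graph size).")
  }
  structure(
    list(n_agents = n_agents, m_attach = m_attach,
         leader_fraction = leader_fraction),
    class = "network_params"
  )
}

new_social_network <- function(n, edges, role) {
  stopifnot(is.matrix(edges), ncol(edges) == 2L)
  adjacency <- Matrix::sparseMatrix(
    i = c(edges[, 1L], edges[, 2L]),
    j = c(edges[, 2L], edges[, 1L]),
    x = 1,
    dims = c(n, n)
  )
  structure(
    list(
      n = n,
      edges = edges,
      adjacency = adjacency,
      degree = as.integer(Matrix::rowSums(adjacency)),
      role = role
    ),
    class = "social_network"
  )
}

#' Build a social interaction network from an explicit edge list
#'
#' Escape hatch for user-supplied networks: any simple undirected graph on
#' nodes `1..n` can be used in place of the generated BA network.
#'
#' @param edges a two-column data frame or matrix of undirected edges
#'   (1-based node ids); may have zero rows.
#' @param n number of nodes; defaults to the largest id in `edges`.
#' @param leader_fraction proportion of highest-degree nodes flagged as
#'   opinion leaders.
#' @return a `social_network` object.
#' @examples
#' star <- social_network(cbind(1, 2:10), n = 10, leader_fraction = 0.1)
#' table(star$role)
#' @export
social_network <- function(edges, n = NULL, leader_fraction = 0.05) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), ncol = 2L)
  storage.mode(edges) <- "integer"
  if (is.null(n)) n <- max(edges)
  n <- check_count(n, "n", min = 1L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) abort_bad_arg("edge ids must lie in 1..n.")
    if (any(edges[, 1L] == edges[, 2L])) abort_bad_arg("self-loops are not allowed.")
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) abort_bad_arg("duplicate edges are not allowed.")
  }
  net <- new_social_network(n, edges, role = rep("ordinary", n))
  assign_opinion_leaders(net, leader_fraction)
}

#' Generate the BA scale-free interaction network
#'
#' Grows a Barabasi-Albert graph: starting from a complete graph on
#' `m_attach + 1` nodes, each subsequent node attaches to `m_attach` distinct
#' existing nodes sampled proportionally to their current degree. The result
#' has exactly `m (N - m - 1) + m (m + 1) / 2` edges and a heavy-tailed
#' degree distribution. The `leader_fraction` highest-degree nodes are
#' assigned the `opinion_leader` role (degree ties broken by ascending id).
#'
#' @param params a [network_params()] object.
#' @param seed integer seed; the construction is deterministic given the seed.
#' @return a `social_network` object with fields `n`, `edges` (integer
#'   matrix), `adjacency` (sparse symmetric matrix), `degree` and `role`.
#' @examples
#' net <- generate_network(network_params(200), seed = 1)
#' sum(net$role == "opinion_leader")
#' @export
generate_network <- function(params, seed = 1L) {
  stopifnot(inherits(params, "network_params"))
  n <- params$n_agents
  m <- params$m_attach
  set.seed(derive_seed(seed, 1L))

  n_seed_edges <- (m * (m + 1L)) %/% 2L
  total_edges <- m * (n - m - 1L) + n_seed_edges
  edges <- matrix(0L, nrow = total_edges, ncol = 2L)

  seed_pairs <- utils::combn(m + 1L, 2L)
  edges[seq_len(n_seed_edges), ] <- cbind(seed_pairs[1L, ], seed_pairs[2L, ])
  deg <- integer(n)
  deg[seq_len(m + 1L)] <- m

  row <- n_seed_edges
  if (n > m + 1L) {
    for (v in seq.int(m + 2L, n)) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, replace = FALSE, prob = deg[existing])
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
      edges[row + seq_len(m), ] <- cbind(targets, v)
      row <- row + m
    }
  }

  net <- new_social_network(n, edges, role = rep("ordinary", n))
  assign_opinion_leaders(net, params$leader_fraction)
}

#' Designate the highest-degree nodes as opinion leaders
#'
#' The `floor(leader_fraction * n)` best-connected nodes take the role
#' `opinion_leader`; everyone else is `ordinary`. Ties at the degree cutoff
#' are broken by ascending node id so the leader set is reproducible.
#'
#' @param network a `social_network`.
#' @param leader_fraction proportion in \[0, 1\].
#' @return the network with its `role` field reassigned.
#' @export
assign_opinion_leaders <- function(network, leader_fraction = 0.05) {
  stopifnot(inherits(network, "social_network"))
  check_prob(leader_fraction, "leader_fraction")
  n_leaders <- floor(leader_fraction * network$n)
  role <- rep("ordinary", network$n)
  if (n_leaders >= 1L) {
    ranking <- order(-network$degree, seq_len(network$n))
    role[ranking[seq_len(n_leaders)]] <- "opinion_leader"
  }
  network$role <- role
  network
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf(
    "<social_network> %d nodes, %d edges, %d opinion leaders\n",
    x$n, nrow(x$edges), sum(x$role == "opinion_leader")
  ))
  invisible(x)
}

#' Export / import a network as plain-text files
#'
#' The edge list is written as a two-column tab-separated file (no header)
#' and node roles as a `node_id<TAB>role` sidecar, so a network can round-trip
#' between runs or be supplied from outside the package.
#'
#' @param network a `social_network`.
#' @param edge_file,role_file paths to write/read.
#' @return `write_network()` returns the paths invisibly; `read_network()`
#'   returns a `social_network`.
#' @export
write_network <- function(network, edge_file, role_file = NULL) {
  stopifnot(inherits(network, "social_network"))
  utils::write.table(network$edges, edge_file, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(role_file)) {
    utils::write.table(
      data.frame(node_id = seq_len(network$n), role = network$role),
      role_file, sep = "\t", row.names = FALSE, col.names = FALSE,
      quote = FALSE
    )
  }
  invisible(c(edge_file, role_file))
}

#' @rdname write_network
#' @export
read_network <- function(edge_file, role_file = NULL) {
  edges <- unname(as.matrix(utils::read.table(edge_file, sep = "\t")))
  if (!is.null(role_file)) {
    roles <- utils::read.table(role_file, sep = "\t",
                               col.names = c("node_id", "role"))
    net <- new_social_network(max(roles$node_id), edges,
                              role = roles$role[order(roles$node_id)])
    net
  } else {
    social_network(edges)
  }
}
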