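## Independent oracles used across the suite. Pure base R, no igraph: the
## betweenness oracle enumerates shortest paths pair by pair so it shares no
## code path with the package implementation.

## BFS distances from every node over an adjacency matrix
bfs_distances <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & !is.finite(d))
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  dist
}

## Enumerate every shortest s-t path (guided by distances-to-t) and count,
## for each node, the geodesics it lies on as an interior vertex.
enumerate_geodesics <- function(adj, dist, s, t) {
  n_paths <- 0L
  interior <- rep(0L, nrow(adj))
  walk <- function(u, path) {
    if (u == t) {
      n_paths <<- n_paths + 1L
      inner <- path[-c(1L, length(path))]
      interior[inner] <<- interior[inner] + 1L
      return(invisible())
    }
    nxt <- which(adj[u, ] > 0 & dist[, t] == dist[u, t] - 1)
    for (v in nxt) walk(v, c(path, v))
  }
  walk(s, s)
  list(n_paths = n_paths, interior = interior)
}

## Component-normalized betweenness by exhaustive geodesic enumeration
bc_oracle <- function(adj) {
  n <- nrow(adj)
  dist <- bfs_distances(adj)
  raw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(dist[s, t]) || dist[s, t] < 2) next
      g <- enumerate_geodesics(adj, dist, s, t)
      raw <- raw + g$interior / g$n_paths
    }
  }
  comp_size <- vapply(seq_len(n), function(v) sum(is.finite(dist[v, ])),
                      numeric(1))
  ifelse(comp_size > 2, raw / ((comp_size - 1) * (comp_size - 2) / 2), 0)
}

## Random simple undirected graph as an adjacency matrix (base R only)
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

adjacency_to_graph <- function(adj) {
  n <- nrow(adj)
  ids <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  build_graph(edges, nodes = ids)
}

## Small default config for fast tests
tiny_config <- function(...) {
  sim_config(n_chaperones = 8L, n_substrates = 60L,
             mean_substrate_multiplicity = 3, chaperone_edge_prob = 0.1,
             n_replicates = 4L, seed = 101L, ...)
}
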