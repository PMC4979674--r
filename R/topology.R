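#' Build a chaperome interaction graph
#'
#' Constructs a simple undirected graph from an edge list: duplicate edges
#' (in either orientation) are collapsed and self-loops are dropped with a
#' warning. Node roles (`"chaperone"` or `"substrate"`) are attached as a
#' vertex attribute; ids without a declared role default to substrate, the
#' safe default for interactor lists where only the chaperone set is known.
#'
#' @param edges Two-column data frame or matrix of node ids (one row per
#'   undirected edge).
#' @param roles Named character vector mapping node id to role.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated.
#' @return An `igraph` object with vertex attribute `role` and graph
#'   attributes `provenance` (`"wild-type"`) and `n_self_loops_dropped`.
#' @export
build_graph <- function(edges, roles = NULL, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (ncol(edges) < 2L) abort("'edges' must have two columns")
    a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
    if (any(!nzchar(a)) || any(!nzchar(b)))
      abort("edge endpoints must be non-empty ids")
    loops <- a == b
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
      a <- a[!loops]; b <- b[!loops]
    }
  } else {
    a <- character(0); b <- character(0)
    loops <- logical(0)
  }
  ids <- unique(c(a, b, nodes, names(roles)))
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = data.frame(name = ids,
                                                           stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  role <- rep("substrate", length(ids))
  if (!is.null(roles)) {
    hit <- match(ids, names(roles))
    role[!is.na(hit)] <- unname(roles[hit[!is.na(hit)]])
  }
  igraph::V(g)$role <- role
  g <- igraph::set_graph_attr(g, "provenance", "wild-type")
  igraph::set_graph_attr(g, "n_self_loops_dropped", sum(loops))
}

#' Delete a node and report orphans
#'
#' Removes a node and all incident edges, emulating an in silico deletion
#' mutant. Neighbours whose only link was to the deleted node are left with
#' degree zero; they are retained in the mutant network and reported as
#' orphans, together with their fraction of the deleted node's interactors.
#'
#' @param network An `igraph` chaperome graph.
#' @param node Node id to delete.
#' @return A list of class `deletion_result`: `network` (the mutant graph,
#'   provenance `"deleted:<node>"`), `deleted`, `deleted_degree`, `orphans`
#'   (ids), `n_orphans`, `orphan_fraction` (orphans / interactors of the
#'   deleted node).
#' @export
delete_node <- function(network, node) {
  if (!node %in% igraph::V(network)$name)
    abort("unknown node '%s'", node)
  nbrs <- igraph::neighbors(network, node)$name
  k <- length(nbrs)
  mutant <- igraph::delete_vertices(network, node)
  orphans <- nbrs[igraph::degree(mutant, nbrs) == 0]
  mutant <- igraph::set_graph_attr(mutant, "provenance",
                                   paste0("deleted:", node))
  structure(list(network = mutant,
                 deleted = node,
                 deleted_degree = k,
                 orphans = orphans,
                 n_orphans = length(orphans),
                 orphan_fraction = if (k > 0) length(orphans) / k else NA_real_),
            class = "deletion_result")
}

#' @export
print.deletion_result <- function(x, ...) {
  cat(sprintf("Deletion mutant: removed %s (degree %d)\n", x$deleted,
              x$deleted_degree))
  cat(sprintf("  %d nodes, %d edges remain; %d orphaned interactor(s) (%.1f%%)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$n_orphans, 100 * x$orphan_fraction))
  invisible(x)
}

#' Node degrees
#'
#' @param network An `igraph` graph.
#' @return A list: `degree` (named integer vector) and `distribution` (data
#'   frame of counts per degree value).
#' @export
node_degree <- function(network) {
  k <- igraph::degree(network)
  tab <- table(k)
  list(degree = k,
       distribution = data.frame(k = as.integer(names(tab)),
                                 n_nodes = as.integer(tab)))
}

#' Neighborhood connectivity
#'
#' Mean degree of each node's neighbours. Undefined (`NA`) for isolated
#' nodes, which are excluded from attribute distributions.
#'
#' @param network An `igraph` graph.
#' @return Named numeric vector.
#' @export
neighborhood_connectivity <- function(network) {
  nm <- igraph::V(network)$name
  if (igraph::ecount(network) == 0L)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  nc <- igraph::knn(network)$knn
  nc[!is.finite(nc)] <- NA_real_
  stats::setNames(as.numeric(nc), nm)
}

#' Local clustering coefficient
#'
#' `C_n = 2 e_n / (k_n (k_n - 1))`, where `e_n` counts connected pairs among
#' the neighbours of `n`. The formula is undefined for degree < 2; those
#' nodes are assigned 0 by convention, and the network average is reported
#' both over all nodes (with that convention) and restricted to nodes of
#' degree >= 2.
#'
#' @param network An `igraph` graph.
#' @return A list: `per_node` (named vector, 0 for degree < 2),
#'   `average_all_nodes`, `average_degree_ge2`.
#' @export
clustering_coefficient <- function(network) {
  nm <- igraph::V(network)$name
  raw <- igraph::transitivity(network, type = "local", isolates = "NaN")
  defined <- is.finite(raw)
  per_node <- ifelse(defined, raw, 0)
  names(per_node) <- nm
  list(per_node = per_node,
       average_all_nodes = if (length(per_node)) mean(per_node) else NaN,
       average_degree_ge2 = if (any(defined)) mean(raw[defined]) else NaN)
}

#' Component-normalized betweenness centrality
#'
#' Shortest-path betweenness with endpoints excluded: for node `p`, the sum
#' over unordered pairs `s, t` (both distinct from `p`) of the fraction of
#' shortest `s`-`t` paths passing through `p`, divided by
#' `(N - 1)(N - 2) / 2`, where `N` is the size of the connected component
#' containing `p`. Values lie in \[0, 1\]; nodes in components of size <= 2
#' (including orphans) get 0.
#'
#' @param network An `igraph` graph.
#' @return Named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(network) {
  raw <- igraph::betweenness(network, directed = FALSE, weights = NA)
  comp <- igraph::components(network)
  N <- comp$csize[comp$membership]
  denom <- (N - 1) * (N - 2) / 2
  bc <- ifelse(N > 2, raw / denom, 0)
  stats::setNames(as.numeric(bc), igraph::V(network)$name)
}

#' Per-node topology profile
#'
#' Computes the four node attributes (degree, neighborhood connectivity,
#' clustering coefficient, component-normalized betweenness) plus component
#' membership for every node.
#'
#' @param network An `igraph` graph.
#' @return A data frame of class `topology_profile` with columns `node`,
#'   `role`, `degree`, `neighborhood_connectivity`, `clustering`,
#'   `betweenness`, `component`, `component_size`; attributes carry the two
#'   clustering averages and the graph provenance.
#' @export
node_topology <- function(network) {
  comp <- igraph::components(network)
  cc <- clustering_coefficient(network)
  out <- data.frame(node = igraph::V(network)$name,
                    role = igraph::V(network)$role %||% "substrate",
                    degree = as.integer(igraph::degree(network)),
                    neighborhood_connectivity = unname(neighborhood_connectivity(network)),
                    clustering = unname(cc$per_node),
                    betweenness = unname(betweenness_centrality(network)),
                    component = comp$membership,
                    component_size = comp$csize[comp$membership],
                    stringsAsFactors = FALSE)
  structure(out,
            avg_clustering_all = cc$average_all_nodes,
            avg_clustering_ge2 = cc$average_degree_ge2,
            provenance = igraph::graph_attr(network, "provenance"),
            class = c("topology_profile", "data.frame"))
}

#' Degree-binned attribute averages
#'
#' Averages a node attribute over all nodes at each observed degree, the
#' form in which attribute distributions of large networks are usually
#' plotted and compared. Nodes with an undefined (`NA`) attribute are
#' excluded from their bin and counted in attribute `n_excluded`.
#'
#' @param profile A [node_topology()] data frame.
#' @param attribute One of `"neighborhood_connectivity"`, `"clustering"`,
#'   `"betweenness"`, `"degree"`.
#' @return Data frame with columns `k`, `mean_value`, `n_nodes`.
#' @export
degree_binned_average <- function(profile, attribute) {
  if (!attribute %in% names(profile))
    abort("unknown attribute '%s'", attribute)
  v <- profile[[attribute]]
  ok <- !is.na(v)
  k <- profile$degree[ok]
  v <- v[ok]
  means <- tapply(v, k, mean)
  counts <- tapply(v, k, length)
  structure(data.frame(k = as.integer(names(means)),
                       mean_value = as.numeric(means),
                       n_nodes = as.integer(counts)),
            n_excluded = sum(!ok))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical cumulative distribution functions; `D` is the
#' maximum absolute ECDF difference and the p-value is the asymptotic
#' two-sided one.
#'
#' @param dist_a,dist_b Numeric samples (non-empty).
#' @return A list with `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(dist_a, dist_b) {
  dist_a <- dist_a[is.finite(dist_a)]
  dist_b <- dist_b[is.finite(dist_b)]
  if (length(dist_a) == 0L || length(dist_b) == 0L)
    abort("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(dist_a, dist_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(dist_a), n_b = length(dist_b))
}

#' Compare attribute distributions between two networks
#'
#' Runs [ks_compare()] on the degree-binned averages (default, the form used
#' for large-network attribute plots) or the raw per-node values of one or
#' more attributes, for a wild-type vs mutant profile pair.
#'
#' @param profile_a,profile_b [node_topology()] data frames.
#' @param attributes Attribute names to compare.
#' @param binned Compare degree-binned averages (default) or per-node values.
#' @return Data frame with `attribute`, `D`, `p_value`.
#' @export
compare_attribute_distributions <- function(profile_a, profile_b,
                                            attributes = c("neighborhood_connectivity",
                                                           "clustering",
                                                           "betweenness"),
                                            binned = TRUE) {
  rows <- lapply(attributes, function(at) {
    if (binned) {
      a <- degree_binned_average(profile_a, at)$mean_value
      b <- degree_binned_average(profile_b, at)$mean_value
    } else {
      a <- profile_a[[at]]; b <- profile_b[[at]]
    }
    ks <- ks_compare(a, b)
    data.frame(attribute = at, D = ks$D, p_value = ks$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
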