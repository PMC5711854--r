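#' Prevalence filter
#'
#' Keeps OTUs detected (count > 0) in strictly more than \code{min_fraction}
#' of the samples — the standard pre-filter before co-abundance network
#' inference.
#'
#' @param table an \code{otu_table}.
#' @param min_fraction prevalence cutoff (study setting: 0.40).
#' @return the filtered \code{otu_table} (possibly with zero OTUs).
#' @export
prevalence_filter <- function(table, min_fraction = 0.40) {
  stopifnot(inherits(table, "otu_table"))
  prev <- colMeans(table$counts > 0)
  subset_otu_table(table, otus = prev > min_fraction)
}

#' Build a correlation network from SparCC output
#'
#' An edge joins OTUs \eqn{i, j} when \eqn{p_{ij} < p_{max}} and
#' \eqn{|R_{ij}| > r_{min}} (both strict). Isolated nodes stay in the node
#' set; the sign of R is preserved on the edge.
#'
#' @param r SparCC correlation matrix.
#' @param p permutation p-value matrix aligned with \code{r}.
#' @param p_max,r_min_abs edge thresholds (study settings: 0.05 and 0.7).
#' @return a \code{co_network}.
#' @export
build_network <- function(r, p, p_max = 0.05, r_min_abs = 0.7) {
  stopifnot(all(dim(r) == dim(p)))
  ids <- rownames(r)
  if (is.null(ids)) ids <- paste0("otu", seq_len(nrow(r)))
  keep <- which(upper.tri(r) & !is.na(p) & p < p_max & abs(r) > r_min_abs,
                arr.ind = TRUE)
  edges <- data.frame(source = ids[keep[, 1]], target = ids[keep[, 2]],
                      r = r[keep], p = p[keep], stringsAsFactors = FALSE)
  co_network(ids, edges,
             params = list(p_max = p_max, r_min_abs = r_min_abs))
}

#' Graph topology summary
#'
#' Scalar metrics and per-node vectors on the unweighted undirected edge
#' set, following the Cytoscape NetworkAnalyzer conventions the study's
#' network statistics use:
#' \itemize{
#' \item clustering coefficient: mean over all nodes, nodes with degree < 2
#'   contributing 0;
#' \item characteristic path length: mean shortest-path length over
#'   connected node pairs (disconnected pairs ignored);
#' \item network centralization: \eqn{\sum_i (d_{max} - d_i) /
#'   ((n-1)(n-2))} (Freeman degree centralization);
#' \item eigenvector centrality: principal eigenvector of the adjacency
#'   matrix restricted to the largest connected component, max-normalized to
#'   1; nodes outside that component score 0.
#' }
#'
#' @param net a \code{co_network}.
#' @param clustering_mode \code{"include_low_degree"} (default, degree < 2
#'   counts as 0) or \code{"exclude"}.
#' @return object of class \code{topology_summary}: list of scalars
#'   (\code{n_nodes}, \code{n_edges}, \code{n_isolated},
#'   \code{characteristic_path_length}, \code{clustering_coefficient},
#'   \code{network_centralization}, \code{avg_num_neighbors},
#'   \code{network_density}, \code{n_components}) plus per-node
#'   \code{degree} and \code{eigenvector_centrality} vectors.
#' @export
topology <- function(net, clustering_mode = c("include_low_degree",
                                              "exclude")) {
  clustering_mode <- match.arg(clustering_mode)
  stopifnot(inherits(net, "co_network"))
  if (!length(net$nodes)) stop("empty node set")
  g <- as_igraph(net)
  n <- length(net$nodes)
  deg <- igraph::degree(g)

  local_cc <- suppressWarnings(igraph::transitivity(g, type = "local",
                                                    isolates = "zero"))
  local_cc[deg < 2] <- 0
  cc <- if (clustering_mode == "include_low_degree") mean(local_cc)
        else if (any(deg >= 2)) mean(local_cc[deg >= 2]) else 0

  sp <- igraph::distances(g)
  finite <- sp[upper.tri(sp)]
  finite <- finite[is.finite(finite) & finite > 0]
  cpl <- if (length(finite)) mean(finite) else NA_real_

  centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  density <- if (n > 1) 2 * nrow(net$edges) / (n * (n - 1)) else 0

  evc <- stats::setNames(numeric(n), net$nodes)
  if (nrow(net$edges)) {
    comp <- igraph::components(g)
    giant <- which(comp$membership == which.max(comp$csize))
    if (length(giant) > 1) {
      sub <- igraph::induced_subgraph(g, giant)
      adj <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
      adj <- (adj > 0) + 0   # unweighted: edge presence only
      ev <- eigen(adj, symmetric = TRUE)
      v <- abs(ev$vectors[, 1])
      evc[igraph::V(g)$name[giant]] <- v / max(v)
    }
  }
  structure(list(n_nodes = n,
                 n_edges = nrow(net$edges),
                 n_isolated = sum(deg == 0),
                 n_components = igraph::components(g)$no,
                 characteristic_path_length = cpl,
                 clustering_coefficient = cc,
                 network_centralization = centralization,
                 avg_num_neighbors = 2 * nrow(net$edges) / n,
                 network_density = density,
                 degree = stats::setNames(as.numeric(deg), net$nodes),
                 eigenvector_centrality = evc),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("topology:", x$n_nodes, "nodes,", x$n_edges, "edges,",
      x$n_isolated, "isolated;",
      "CPL", round(x$characteristic_path_length, 3),
      "CC", round(x$clustering_coefficient, 3),
      "centralization", round(x$network_centralization, 3),
      "density", round(x$network_density, 3), "\n")
  invisible(x)
}

topology_scalars <- function(x)
  unlist(x[c("n_nodes", "n_edges", "n_isolated", "n_components",
             "characteristic_path_length", "clustering_coefficient",
             "network_centralization", "avg_num_neighbors",
             "network_density")])

#' Compare the topologies of two networks
#'
#' Two-sample Kolmogorov-Smirnov tests (asymptotic p) on the degree
#' distributions and on the eigenvector-centrality distributions, plus a
#' side-by-side table of the scalar metrics.
#'
#' @param a,b \code{topology_summary} objects.
#' @return list with \code{ks_degree} and \code{ks_centrality} (each
#'   \code{list(statistic, p_value)}) and \code{metrics} (data.frame with
#'   one row per scalar metric, columns \code{a} and \code{b}).
#' @export
compare_topologies <- function(a, b) {
  stopifnot(inherits(a, "topology_summary"), inherits(b, "topology_summary"))
  ks <- function(x, y) {
    if (length(x) < 2 || length(y) < 2)
      stop("KS comparison needs at least 2 values per network")
    t <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  sa <- topology_scalars(a)
  sb <- topology_scalars(b)
  list(ks_degree = ks(a$degree, b$degree),
       ks_centrality = ks(a$eigenvector_centrality,
                          b$eigenvector_centrality),
       metrics = data.frame(metric = names(sa), a = unname(sa),
                            b = unname(sb), stringsAsFactors = FALSE))
}
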