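#' Sample-by-sample distance matrix
#'
#' A full symmetric non-negative matrix with zero diagonal and sample ids as
#' dimnames.
#'
#' @param m square numeric matrix with matching dimnames.
#' @return the validated matrix with class \code{distance_matrix}.
#' @export
distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("distance matrix needs identical row/column sample ids")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be exactly 0")
  structure(m, class = c("distance_matrix", "matrix"))
}

#' Write / read a distance matrix as TSV (round-trip safe to 1e-12)
#' @param dm a \code{distance_matrix}.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  out <- c(paste(c("sample_id", colnames(dm)), collapse = "\t"),
           vapply(seq_len(nrow(dm)), function(i)
             paste(c(rownames(dm)[i], fmt(dm[i, ])), collapse = "\t"), ""))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  m <- (m + t(m)) / 2          # absorb last-digit asymmetry from text round-trip
  diag(m) <- 0
  distance_matrix(m)
}

#' Correlation co-abundance network
#'
#' Nodes are the OTUs that passed the prevalence filter; edges are the
#' unordered pairs whose SparCC correlation and permutation p-value survive
#' the thresholds. Isolated nodes are retained in the node set.
#'
#' @param nodes character vector of OTU ids.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{r}, \code{p}.
#' @param params list of the thresholds used (recorded, not re-applied).
#' @return object of class \code{co_network}.
#' @export
co_network <- function(nodes, edges, params = list()) {
  edges <- as.data.frame(edges)
  if (!nrow(edges))
    edges <- data.frame(source = character(), target = character(),
                        r = numeric(), p = numeric())
  if (!all(c("source", "target", "r", "p") %in% names(edges)))
    stop("edges need columns source, target, r, p")
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("edge endpoints missing from node set")
  if (nrow(edges)) {
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target), sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  structure(list(nodes = as.character(nodes), edges = edges, params = params),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("co-abundance network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "r", "p")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Write / read a correlation network
#'
#' \code{edge_tsv} writes one row per edge with columns
#' \code{source, target, R, p} (isolated nodes are listed in a companion
#' \code{<path>.nodes} file so round-trips preserve the node set);
#' \code{graphml} goes through igraph and keeps attributes at full precision.
#'
#' @param net a \code{co_network}.
#' @param path output file.
#' @param format \code{"edge_tsv"} or \code{"graphml"}.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "co_network"))
  if (format == "edge_tsv") {
    fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
    out <- c("source\ttarget\tR\tp",
             if (nrow(net$edges))
               paste(net$edges$source, net$edges$target, fmt(net$edges$r),
                     fmt(net$edges$p), sep = "\t"))
    writeLines(out, path)
    writeLines(net$nodes, paste0(path, ".nodes"))
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "numeric"))
    names(df) <- c("source", "target", "r", "p")
    nodes_file <- paste0(path, ".nodes")
    nodes <- if (file.exists(nodes_file)) readLines(nodes_file)
             else unique(c(df$source, df$target))
    co_network(nodes, df)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    names(ed)[names(ed) == "from"] <- "source"
    names(ed)[names(ed) == "to"] <- "target"
    co_network(igraph::V(g)$name, ed[, c("source", "target", "r", "p")])
  }
}
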