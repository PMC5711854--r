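#' Hellinger transform
#'
#' \eqn{A_{ij} = \sqrt{n_{ij} / N_j}} where \eqn{N_j} is the total count of
#' sample \eqn{j}: the square root of relative abundance. Each transformed
#' row has unit Euclidean norm, which makes Euclidean distances (and hence
#' RDA) well-behaved on compositions and removes depth differences.
#'
#' @param table an \code{otu_table} (averaged rarefied tables accepted).
#' @return a \code{transformed_table}: list with \code{sample_ids},
#'   \code{otu_ids} and \code{values} (samples x OTUs matrix in [0,1]).
#' @export
hellinger <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "))
  values <- sqrt(table$counts / totals)
  structure(list(sample_ids = table$sample_ids, otu_ids = table$otu_ids,
                 values = values),
            class = "transformed_table")
}

#' @export
print.transformed_table <- function(x, ...) {
  cat("Hellinger table:", length(x$sample_ids), "samples x",
      length(x$otu_ids), "OTUs\n")
  invisible(x)
}

proportions_matrix <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "))
  table$counts / totals
}

#' Per-sample alpha diversity
#'
#' \code{observed_otus}: number of OTUs with non-zero count.
#' \code{shannon}: \eqn{-\sum p \log_2 p} over non-zero proportions (base-2,
#' the QIIME 1 convention). \code{faith_pd}: total branch length of the
#' minimal subtree connecting the observed OTUs to the root (PD_whole_tree
#' convention: the path to the root is included).
#'
#' @param table an \code{otu_table}.
#' @param metric one of \code{"observed_otus"}, \code{"shannon"},
#'   \code{"faith_pd"}.
#' @param tree rooted \code{ape::phylo} with branch lengths, required for
#'   \code{faith_pd}; its tips must cover every OTU observed in the table.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("observed_otus", "shannon",
                                              "faith_pd"), tree = NULL) {
  stopifnot(inherits(table, "otu_table"))
  metric <- match.arg(metric)
  m <- table$counts
  out <- switch(metric,
    observed_otus = rowSums(m > 0),
    shannon = vegan::diversity(m, index = "shannon", base = 2),
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a phylogenetic tree")
      if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
      observed <- table$otu_ids[colSums(m > 0) > 0]
      missing <- setdiff(observed, tree$tip.label)
      if (length(missing))
        stop("OTUs observed but missing from the tree: ",
             paste(missing, collapse = ", "))
      picante::pd(m, tree, include.root = TRUE)$PD
    })
  stats::setNames(as.numeric(out), table$sample_ids)
}

bc_pair <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

#' Bray-Curtis distance matrix
#'
#' \eqn{d(x, y) = 1 - 2\sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}.
#' Computed on per-sample proportions by default (Bray-Curtis on raw counts
#' is depth-sensitive; a raw-count mode is kept for rarefied tables).
#'
#' @param table an \code{otu_table}.
#' @param on \code{"proportions"} (default) or \code{"counts"}.
#' @return a \code{distance_matrix}.
#' @export
bray_curtis <- function(table, on = c("proportions", "counts")) {
  on <- match.arg(on)
  stopifnot(inherits(table, "otu_table"))
  x <- if (on == "proportions") proportions_matrix(table) else {
    if (any(rowSums(table$counts) <= 0))
      stop("all-zero sample(s): ",
           paste(table$sample_ids[rowSums(table$counts) <= 0], collapse = ", "))
    table$counts
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  distance_matrix(d)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres \eqn{-\frac12 D^2}, eigendecomposes, and embeds on the
#' axes with positive eigenvalues. Negative eigenvalues are clamped to zero
#' and excluded from the proportion-explained denominator; no Lingoes or
#' Cailliez correction is applied.
#'
#' @param dm a \code{distance_matrix}.
#' @param n_axes number of axes to return (capped at n_samples - 1).
#' @return an \code{ordination} object: list with \code{coordinates}
#'   (samples x axes), \code{eigenvalues} (all, non-increasing),
#'   \code{proportion_explained} and \code{method = "pcoa"}.
#' @export
pcoa <- function(dm, n_axes = 2) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- nrow(dm)
  if (n_axes < 1) stop("n_axes must be >= 1")
  n_axes <- min(n_axes, n - 1)
  d2 <- unclass(dm)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  pos <- pmax(lambda, 0)
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  prop <- if (sum(pos) > 0) pos / sum(pos) else rep(0, n)
  structure(list(coordinates = coords, eigenvalues = lambda,
                 proportion_explained = prop, method = "pcoa"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes;",
      "axis-1 proportion", round(x$proportion_explained[1], 3), "\n")
  invisible(x)
}

#' Bray-Curtis distance of each post-baseline sample to its baseline centroid
#'
#' The baseline of a reference unit (the sample's group, or its subject) is
#' the mean proportion vector over that unit's samples with
#' \code{timepoint < 0}. Each sample with \code{timepoint >= 0} is scored by
#' its Bray-Curtis distance to that centroid, giving the deviation-from-
#' baseline trajectory.
#'
#' @param table an \code{otu_table}.
#' @param meta \code{sample_metadata} with \code{timepoint} (and
#'   \code{subject} for the subject mode).
#' @param reference \code{"group_baseline_centroid"} or
#'   \code{"subject_baseline"}.
#' @return data.frame: sample_id, group, subject, timepoint, distance.
#' @export
distance_to_baseline <- function(table, meta,
                                 reference = c("group_baseline_centroid",
                                               "subject_baseline")) {
  reference <- match.arg(reference)
  meta <- match_meta(table, meta)
  if (!"timepoint" %in% names(meta)) stop("metadata lacks 'timepoint'")
  unit <- if (reference == "group_baseline_centroid") meta$group else {
    if (!"subject" %in% names(meta)) stop("metadata lacks 'subject'")
    meta$subject
  }
  props <- proportions_matrix(table)
  base_idx <- which(meta$timepoint < 0)
  post_idx <- which(meta$timepoint >= 0)
  no_base <- setdiff(unique(unit[post_idx]), unique(unit[base_idx]))
  if (length(no_base))
    stop("reference unit(s) with no baseline samples: ",
         paste(no_base, collapse = ", "))
  centroids <- lapply(split(base_idx, unit[base_idx]), function(i)
    colMeans(props[i, , drop = FALSE]))
  d <- vapply(post_idx, function(i)
    bc_pair(props[i, ], centroids[[as.character(unit[i])]]), 0)
  data.frame(sample_id = table$sample_ids[post_idx],
             group = meta$group[post_idx],
             subject = if ("subject" %in% names(meta)) meta$subject[post_idx]
                       else NA_character_,
             timepoint = meta$timepoint[post_idx],
             distance = d,
             stringsAsFactors = FALSE)
}
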