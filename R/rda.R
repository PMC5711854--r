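#' Two-group redundancy analysis on a Hellinger-transformed table
#'
#' With a single binary constraint the constrained subspace of RDA is
#' one-dimensional: the direction joining the two group centroids of the
#' column-centred Hellinger matrix. The fraction of each OTU's variability
#' explained by genotype is the R-squared of that OTU's Hellinger column
#' regressed on the group indicator (equivalently its between-group sum of
#' squares over its total sum of squares); the overall constrained
#' proportion is the ratio of the summed between-group SS to the total SS.
#'
#' @param A a \code{transformed_table} (see \code{\link{hellinger}}).
#' @param meta \code{sample_metadata}.
#' @param group_pair length-2 character: (reference group, contrast group).
#' @param n_axes total ordination axes to return (axis 1 is the constrained
#'   axis; further axes are principal components of the residuals).
#' @return list with \code{ordination} (class \code{ordination}, method
#'   \code{"rda"}), \code{variance_explained} (named per-OTU fractions in
#'   [0,1]), \code{constrained_proportion}, \code{group_pair} and
#'   \code{mean_diff} (reference minus contrast Hellinger group means,
#'   used for enrichment direction).
#' @export
rda_two_group <- function(A, meta, group_pair, n_axes = 2) {
  stopifnot(inherits(A, "transformed_table"), length(group_pair) == 2)
  meta <- meta[match(A$sample_ids, meta$sample_id), , drop = FALSE]
  keep <- meta$group %in% group_pair
  if (!all(keep)) {
    A <- list(sample_ids = A$sample_ids[keep], otu_ids = A$otu_ids,
              values = A$values[keep, , drop = FALSE])
    class(A) <- "transformed_table"
    meta <- meta[keep, , drop = FALSE]
  }
  g <- factor(meta$group, levels = group_pair)
  n_by <- table(g)
  if (any(n_by < 2))
    stop("each group needs >= 2 samples (got ",
         paste(n_by, collapse = ", "), ")")
  Y <- scale(A$values, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  mean_ref <- colMeans(Y[g == group_pair[1], , drop = FALSE])
  mean_con <- colMeans(Y[g == group_pair[2], , drop = FALSE])
  fitted <- matrix(0, n, ncol(Y))
  fitted[g == group_pair[1], ] <- matrix(mean_ref, sum(g == group_pair[1]),
                                         ncol(Y), byrow = TRUE)
  fitted[g == group_pair[2], ] <- matrix(mean_con, sum(g == group_pair[2]),
                                         ncol(Y), byrow = TRUE)
  ss_fit <- colSums(fitted^2)
  ss_tot <- colSums(Y^2)
  varexp <- ifelse(ss_tot > 0, ss_fit / ss_tot, 0)
  names(varexp) <- A$otu_ids

  diff <- mean_ref - mean_con
  nd <- sqrt(sum(diff^2))
  w <- if (nd > 0) diff / nd else diff
  axis1 <- drop(Y %*% w)
  resid <- Y - fitted
  lambda1 <- sum((fitted %*% w)^2) / (n - 1)
  total_inertia <- sum(ss_tot) / (n - 1)

  extra <- max(0, n_axes - 1)
  coords <- matrix(axis1, ncol = 1)
  lambdas <- lambda1
  if (extra > 0 && any(abs(resid) > 0)) {
    pc <- prcomp(resid, center = FALSE)
    k <- min(extra, ncol(pc$x))
    coords <- cbind(coords, pc$x[, seq_len(k), drop = FALSE])
    lambdas <- c(lambdas, pc$sdev[seq_len(k)]^2)
  }
  rownames(coords) <- A$sample_ids
  colnames(coords) <- c("RDA1", if (ncol(coords) > 1)
    paste0("PC", seq_len(ncol(coords) - 1)))
  ord <- structure(list(coordinates = coords, eigenvalues = lambdas,
                        proportion_explained = lambdas / total_inertia,
                        method = "rda"),
                   class = "ordination")
  list(ordination = ord,
       variance_explained = varexp,
       constrained_proportion = sum(ss_fit) / sum(ss_tot),
       group_pair = group_pair,
       mean_diff = stats::setNames(diff, A$otu_ids))
}

#' Select key OTUs by variance explained and assign enrichment direction
#'
#' OTUs whose genotype-explained fraction of variability exceeds
#' \code{threshold} are key OTUs. Each is assigned to \code{N} (enriched in
#' the reference group) or \code{M} (enriched in the contrast group) by the
#' sign of the difference of Hellinger group means; zero-difference OTUs are
#' excluded.
#'
#' @param rda_fit result of \code{\link{rda_two_group}}.
#' @param threshold variance-explained cutoff (strictly greater-than);
#'   default 0.10.
#' @return object of class \code{key_otu_set}: list with \code{N}, \code{M}
#'   (character vectors), \code{variance_explained} (named, members only)
#'   and \code{threshold}.
#' @export
select_key_otus <- function(rda_fit, threshold = 0.10) {
  varexp <- rda_fit$variance_explained
  diff <- rda_fit$mean_diff
  sel <- names(varexp)[varexp > threshold & diff != 0]
  N <- sel[diff[sel] > 0]
  M <- sel[diff[sel] < 0]
  if (!length(N) || !length(M))
    stop("key-OTU selection leaves an empty set (|N| = ", length(N),
         ", |M| = ", length(M), "); the index is undefined")
  structure(list(N = N, M = M,
                 variance_explained = varexp[sel],
                 threshold = threshold,
                 group_pair = rda_fit$group_pair),
            class = "key_otu_set")
}

#' @export
print.key_otu_set <- function(x, ...) {
  cat("key OTU set: |N| =", length(x$N), "(reference-enriched), |M| =",
      length(x$M), "(contrast-enriched), threshold", x$threshold, "\n")
  invisible(x)
}
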