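#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Midrank U statistic. The p-value is exact (enumeration-equivalent) when
#' the combined sample size is at most 12 and there are no ties, and a
#' normal approximation with tie correction otherwise (no continuity
#' correction, so identical samples give p = 1).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return object of class \code{test_result}: list with \code{statistic}
#'   (U for \code{x}), \code{p_value}, \code{method}, \code{n}.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 12
  wt <- suppressWarnings(
    if (exact) stats::wilcox.test(x, y, exact = TRUE)
    else stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 method = if (exact) "mann_whitney_exact"
                          else "mann_whitney_normal",
                 n = c(length(x), length(y))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 6),
      ", p = ", signif(x$p_value, 4),
      if (!is.null(x$adjusted_p)) paste0(", adj p = ",
                                         signif(x$adjusted_p, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values (same order).
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' MANOVA on retained principal coordinates
#'
#' Runs PCoA on the distance matrix, retains the smallest number of axes
#' whose cumulative proportion of (positive) eigenvalue mass reaches
#' \code{variance_target}, and tests group separation with a one-way MANOVA
#' using Pillai's trace (Wilks available). With a single retained axis the
#' test reduces to a one-way ANOVA F test.
#'
#' @param dm a \code{distance_matrix}.
#' @param meta \code{sample_metadata} covering the samples of \code{dm}.
#' @param variance_target cumulative variance fraction to retain (study
#'   setting: 0.80).
#' @param statistic \code{"Pillai"} or \code{"Wilks"}.
#' @return a \code{test_result} with fields \code{statistic} (trace),
#'   \code{f_value}, \code{p_value}, \code{n_axes}, \code{method}.
#' @export
manova_on_pcs <- function(dm, meta, variance_target = 0.80,
                          statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- rownames(dm)
  i <- match(ids, meta$sample_id)
  if (anyNA(i)) stop("samples missing from metadata")
  g <- factor(meta$group[i])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- length(ids)
  ord <- pcoa(dm, n_axes = n - 1)
  cum <- cumsum(ord$proportion_explained)
  k <- which(cum >= variance_target)[1]
  if (is.na(k)) k <- n - 1
  if (k >= n - nlevels(g))
    stop("retained axes (", k, ") >= residual df; within-group covariance ",
         "singular")
  X <- ord$coordinates[, seq_len(k), drop = FALSE]
  if (k == 1) {
    fit <- stats::anova(stats::lm(X[, 1] ~ g))
    res <- list(statistic = fit[1, "Sum Sq"] /
                  (fit[1, "Sum Sq"] + fit[2, "Sum Sq"]),
                f_value = fit[1, "F value"], p_value = fit[1, "Pr(>F)"],
                n_axes = 1L, method = "anova_on_pc1",
                n = as.vector(base::table(g)))
  } else {
    fit <- stats::manova(X ~ g)
    s <- summary(fit, test = statistic)$stats
    res <- list(statistic = s[1, 2], f_value = s[1, "approx F"],
                p_value = s[1, "Pr(>F)"], n_axes = k,
                method = paste0("manova_", tolower(statistic)),
                n = as.vector(base::table(g)))
  }
  structure(res, class = "test_result")
}

lineage_rank <- function(lineage, rank = "phylum") {
  prefix <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__", species = "s__")[rank]
  vapply(strsplit(lineage, ";"), function(parts) {
    parts <- trimws(parts)
    hit <- grep(paste0("^", prefix), parts, value = TRUE)
    val <- if (length(hit)) sub(prefix, "", hit[1]) else ""
    if (!nzchar(val)) "Unclassified" else val
  }, "")
}

#' Per-taxon differential relative abundance between two groups
#'
#' Collapses relative abundances to the requested taxonomic rank, runs a
#' two-sided Mann-Whitney test per taxon between the two groups, and adjusts
#' across taxa with Benjamini-Hochberg. OTUs lacking the rank fall into an
#' \code{Unclassified} bucket.
#'
#' @param table an \code{otu_table} with taxonomy.
#' @param meta \code{sample_metadata}.
#' @param group_pair the two group labels to compare.
#' @param rank taxonomic rank, default \code{"phylum"}.
#' @return data.frame: taxon, mean relative abundance per group, U
#'   statistic, p_value, adjusted_p; sorted by p.
#' @export
phylum_abundance_test <- function(table, meta, group_pair, rank = "phylum") {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy)) stop("table has no taxonomy")
  meta <- match_meta(table, meta)
  keep <- meta$group %in% group_pair
  tab <- subset_otu_table(table, samples = keep)
  meta <- meta[keep, , drop = FALSE]
  props <- proportions_matrix(tab)
  lin <- table$taxonomy[tab$otu_ids]
  lin[is.na(lin)] <- ""
  taxon <- lineage_rank(lin, rank)
  agg <- t(rowsum(t(props), group = taxon))
  ga <- meta$group == group_pair[1]
  res <- do.call(rbind, lapply(colnames(agg), function(tx) {
    t <- mann_whitney(agg[ga, tx], agg[!ga, tx])
    data.frame(taxon = tx,
               mean_a = mean(agg[ga, tx]), mean_b = mean(agg[!ga, tx]),
               statistic = t$statistic, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  res$adjusted_p <- bh_fdr(res$p_value)
  res[order(res$p_value), ]
}

#' Kruskal-Wallis multi-group extension (thin wrapper)
#' @param values numeric vector.
#' @param groups group labels aligned with \code{values}.
#' @return a \code{test_result}.
#' @export
kruskal_groups <- function(values, groups) {
  kt <- stats::kruskal.test(values, factor(groups))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 method = "kruskal_wallis",
                 n = as.vector(base::table(groups))),
            class = "test_result")
}
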